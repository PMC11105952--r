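SOURCE_DBS <- c("KEGG_PATHWAY", "KEGG_DISEASE", "GO_BP", "GO_MF", "GO_CC")
ANNOTATION_ORGANISMS <- c("ZEBRAFISH", "HUMAN_VIA_ORTHOLOGY")

#' Construct a gene-set collection
#'
#' A collection of named gene sets (KEGG pathways, KEGG diseases, or GO
#' terms) whose member genes all live in one declared namespace and
#' organism. Each set carries an \code{annotation_organism} recording
#' whether its membership comes from native zebrafish annotation or was
#' projected from human annotation through orthology; the pair
#' \code{(set_id, annotation_organism)} is unique within a collection.
#'
#' @param ids character vector of set identifiers (e.g. \code{"dre04010"},
#'   \code{"GO:0008150"}).
#' @param set_names human-readable set names (recycled from \code{ids} if
#'   missing).
#' @param members list of character vectors of member gene IDs; duplicates
#'   within a set are collapsed, and every set must keep at least one
#'   member.
#' @param source_db one of \code{KEGG_PATHWAY}, \code{KEGG_DISEASE},
#'   \code{GO_BP}, \code{GO_MF}, \code{GO_CC}; scalar or per-set vector.
#' @param annotation_organism \code{ZEBRAFISH} or
#'   \code{HUMAN_VIA_ORTHOLOGY}; scalar or per-set vector.
#' @param namespace gene-ID namespace of the members.
#' @param organism organism of the member gene IDs (\code{"zebrafish"} or
#'   \code{"human"}).
#' @return A \code{gene_set_collection}.
#' @export
gene_set_collection <- function(ids, set_names = ids, members,
                                source_db = "KEGG_PATHWAY",
                                annotation_organism = "ZEBRAFISH",
                                namespace = "symbol",
                                organism = "zebrafish") {
  ids <- as.character(ids)
  stopifnot(is.list(members), length(members) == length(ids),
            length(set_names) == length(ids))
  check_enum <- function(x, choices, arg) {
    x <- toupper(as.character(x))
    bad <- !x %in% choices
    if (any(bad))
      stop(sprintf("invalid %s '%s'; valid values: %s", arg, x[bad][1],
                   paste(choices, collapse = ", ")), call. = FALSE)
    x
  }
  source_db <- rep_len(check_enum(source_db, SOURCE_DBS, "source_db"),
                       length(ids))
  annotation_organism <- rep_len(
    check_enum(annotation_organism, ANNOTATION_ORGANISMS,
               "annotation_organism"), length(ids))
  members <- lapply(members, function(m) {
    m <- trim_ids(m)
    unique(m[!is.na(m)])
  })
  sizes <- lengths(members)
  if (any(sizes < 1L))
    stop("every gene set must have at least one member; empty: ",
         paste(ids[sizes < 1L], collapse = ", "), call. = FALSE)
  key <- paste(ids, annotation_organism, sep = "\r")
  if (anyDuplicated(key))
    stop("duplicate (set_id, annotation_organism) pairs: ",
         paste(unique(ids[duplicated(key)]), collapse = ", "),
         call. = FALSE)
  structure(list(ids = ids,
                 set_names = as.character(set_names),
                 members = members,
                 source_db = source_db,
                 annotation_organism = annotation_organism,
                 namespace = match_namespace(namespace),
                 organism = match.arg(tolower(organism),
                                      c("zebrafish", "human"))),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$ids)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("Gene-set collection: ", length(x), " sets (",
      x$organism, " genes, ", x$namespace, " IDs)\n", sep = "")
  tab <- table(x$annotation_organism)
  cat("  annotation: ",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n", sep = "")
  cat("  set sizes: ", paste(range(lengths(x$members)), collapse = "-"),
      " genes\n", sep = "")
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$ids)
  if (anyNA(i)) stop("unknown set id(s) in subset", call. = FALSE)
  gene_set_collection(x$ids[i], x$set_names[i], x$members[i],
                      x$source_db[i], x$annotation_organism[i],
                      x$namespace, x$organism)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: one set per line,
#' \code{set_id<TAB>description<TAB>gene1<TAB>gene2...}. Lines with fewer
#' than three fields are a format error (reported with the line number);
#' duplicate member genes within a line are collapsed. Collection-level
#' metadata may be supplied as leading comment lines
#' (\code{# namespace: symbol}, \code{# organism: zebrafish},
#' \code{# source_db: KEGG_PATHWAY},
#' \code{# annotation_organism: ZEBRAFISH}) or through the arguments,
#' which take precedence.
#'
#' @param path path to the GMT file.
#' @param namespace,organism,source_db,annotation_organism collection
#'   metadata; \code{NULL} means take from file header, falling back to
#'   symbol/zebrafish/KEGG_PATHWAY/ZEBRAFISH.
#' @return A \code{\link{gene_set_collection}}.
#' @export
read_gmt <- function(path, namespace = NULL, organism = NULL,
                     source_db = NULL, annotation_organism = NULL) {
  if (!file.exists(path)) stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  meta <- list(namespace = "symbol", organism = "zebrafish",
               source_db = "KEGG_PATHWAY", annotation_organism = "ZEBRAFISH")
  hdr <- grep("^#", lines)
  for (i in hdr) {
    m <- regmatches(lines[i],
                    regexec("^#\\s*([a-z_]+)\\s*:\\s*(\\S+)", lines[i]))[[1]]
    if (length(m) == 3L && m[2] %in% names(meta)) meta[[m[2]]] <- m[3]
  }
  for (a in names(meta)) {
    v <- get(a)
    if (!is.null(v)) meta[[a]] <- v
  }
  body <- setdiff(seq_along(lines), hdr)
  body <- body[nzchar(trimws(lines[body]))]
  fields <- strsplit(lines[body], "\t", fixed = TRUE)
  short <- lengths(fields) < 3L
  if (any(short))
    stop("GMT format error: fewer than 3 tab-separated fields at line ",
         body[which(short)[1]], call. = FALSE)
  per_org <- rep_len(meta$annotation_organism, length(fields))
  gene_set_collection(
    ids = vapply(fields, `[[`, "", 1L),
    set_names = vapply(fields, `[[`, "", 2L),
    members = lapply(fields, function(f) f[-(1:2)]),
    source_db = meta$source_db,
    annotation_organism = per_org,
    namespace = meta$namespace,
    organism = meta$organism)
}

#' Write a gene-set collection to a GMT file
#'
#' Inverse of \code{\link{read_gmt}} up to within-set member order: members
#' are emitted in lexicographic order so output bytes are stable. The
#' collection metadata is written as \code{#} header lines, so a
#' write/read round trip reproduces the collection exactly (member order
#' aside, which is never semantically meaningful).
#'
#' @param collection a \code{\link{gene_set_collection}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write GMT file: ", path,
                                           call. = FALSE))
  on.exit(close(con))
  hdr <- c(sprintf("# namespace: %s", collection$namespace),
           sprintf("# organism: %s", collection$organism))
  if (length(collection))
    hdr <- c(hdr,
             sprintf("# source_db: %s", collection$source_db[1]),
             sprintf("# annotation_organism: %s",
                     collection$annotation_organism[1]))
  writeLines(hdr, con)
  if (length(collection))
    writeLines(vapply(seq_along(collection$ids), function(i) {
      paste(c(collection$ids[i], collection$set_names[i],
              sort(collection$members[[i]], method = "radix")),
            collapse = "\t")
    }, ""), con)
  invisible(path)
}

#' Retrieve the member genes of one set, in any namespace
#'
#' Looks up a set by its ID and returns the member genes, optionally
#' converted to another namespace through a mapping table. Members that do
#' not convert are attached as the \code{"unmapped"} attribute rather than
#' silently dropped.
#'
#' @param collection a \code{\link{gene_set_collection}}.
#' @param set_id the set identifier.
#' @param target_ns namespace to return genes in; default the collection's
#'   own (members returned verbatim).
#' @param mapping a \code{\link{mapping_table}}; required when converting.
#' @param case_insensitive passed to \code{\link{convert_ids}}.
#' @return Character vector of gene IDs with an \code{"unmapped"}
#'   attribute.
#' @export
genes_in_set <- function(collection, set_id, target_ns = NULL,
                         mapping = NULL, case_insensitive = FALSE) {
  stopifnot(inherits(collection, "gene_set_collection"))
  i <- match(set_id, collection$ids)
  if (is.na(i)) {
    near <- collection$ids[order(utils::adist(set_id, collection$ids))]
    stop("unknown set id '", set_id, "'; nearest: ",
         paste(utils::head(near, 3), collapse = ", "), call. = FALSE)
  }
  members <- collection$members[[i]]
  if (is.null(target_ns) ||
      match_namespace(target_ns, "target_ns") == collection$namespace) {
    attr(members, "unmapped") <- character(0)
    return(members)
  }
  if (is.null(mapping))
    stop("a mapping table is required to convert to '", target_ns, "'",
         call. = FALSE)
  cv <- convert_ids(members, collection$namespace, target_ns, mapping,
                    case_insensitive = case_insensitive)
  out <- unique(cv$mapped$output)
  attr(out, "unmapped") <- cv$unmapped
  out
}

#' Cross-organism counterpart key of a set identifier
#'
#' KEGG pathway maps are the same pathway in every organism, distinguished
#' only by a three-letter organism prefix (\code{dre04010} and
#' \code{hsa04010} are both map 04010), so the counterpart key of a KEGG
#' pathway ID is its map number. GO identifiers are organism-agnostic and
#' KEGG disease identifiers (\code{H}-numbers) are annotated for human
#' only, so both are returned unchanged.
#'
#' @param set_id character vector of KEGG pathway, KEGG disease, or GO
#'   identifiers.
#' @return Character vector of counterpart keys.
#' @examples
#' counterpart_key(c("dre04010", "hsa04010", "GO:0008150", "H00286"))
#' @export
counterpart_key <- function(set_id) {
  set_id <- trim_ids(set_id)
  out <- character(length(set_id))
  for (i in seq_along(set_id)) {
    id <- set_id[i]
    if (is.na(id)) stop("empty set_id", call. = FALSE)
    if (grepl("^GO:[0-9]+$", id) || grepl("^H[0-9]{5}$", id)) {
      out[i] <- id
    } else if (grepl("^[a-z]{3,4}[0-9]{5}$", id)) {
      out[i] <- sub("^[a-z]+", "", id)
    } else {
      stop("cannot parse KEGG-style set id '", id,
           "' (expected e.g. dre04010, hsa04010, GO:0008150, H00286)",
           call. = FALSE)
    }
  }
  out
}

#' Project a human gene-set collection into zebrafish gene space
#'
#' Replaces every human set's members by the union of all zebrafish
#' orthologs of those members (many-to-many expansion through the teleost
#' genome duplication), marking each set
#' \code{annotation_organism = "HUMAN_VIA_ORTHOLOGY"}. Sets left with fewer
#' than \code{min_size} zebrafish genes are dropped and listed in the
#' \code{"dropped"} attribute: tiny projected sets make both enrichment
#' tests degenerate.
#'
#' @param human_collection a \code{\link{gene_set_collection}} with
#'   \code{organism = "human"}.
#' @param ortho an \code{\link{orthology_table}}.
#' @param min_size minimum surviving member count (default 5).
#' @return A zebrafish-namespace \code{gene_set_collection} with a
#'   \code{"dropped"} attribute (data.frame \code{set_id},
#'   \code{n_orthologs}).
#' @export
orthologize_collection <- function(human_collection, ortho, min_size = 5L) {
  stopifnot(inherits(human_collection, "gene_set_collection"),
            inherits(ortho, "orthology_table"))
  if (human_collection$organism != "human")
    stop("collection to orthologize must have organism = 'human'",
         call. = FALSE)
  proj <- lapply(human_collection$members, function(m) {
    unique(ortho$zfish_id[ortho$human_id %in% m])
  })
  n <- lengths(proj)
  keep <- n >= min_size
  dropped <- data.frame(set_id = human_collection$ids[!keep],
                        n_orthologs = n[!keep], stringsAsFactors = FALSE)
  if (!any(keep))
    stop("no set survives orthology projection at min_size = ", min_size,
         call. = FALSE)
  out <- gene_set_collection(
    ids = human_collection$ids[keep],
    set_names = human_collection$set_names[keep],
    members = proj[keep],
    source_db = human_collection$source_db[keep],
    annotation_organism = "HUMAN_VIA_ORTHOLOGY",
    namespace = attr(ortho, "zfish_ns"),
    organism = "zebrafish")
  attr(out, "dropped") <- dropped
  out
}

#' Merge zebrafish-native and orthology-derived collections
#'
#' Combines a zebrafish-annotated collection with a human collection
#' already projected into zebrafish gene space
#' (\code{\link{orthologize_collection}}). Mode \code{"all"} keeps both
#' versions of every pathway, disambiguated by their annotation organism.
#' Mode \code{"novel_only"} treats zebrafish annotation as ground truth:
#' it keeps all zebrafish sets and adds only those human-derived sets
#' whose \code{\link{counterpart_key}} matches no zebrafish set — i.e.
#' pathways (and all human-only KEGG diseases) that zebrafish annotation
#' lacks entirely.
#'
#' @param zfish zebrafish-native \code{\link{gene_set_collection}}.
#' @param human_ortho orthology-projected collection in the same (zebrafish)
#'   namespace; may be empty (\code{NULL}).
#' @param mode \code{"all"} or \code{"novel_only"}.
#' @return A merged \code{gene_set_collection}.
#' @export
merge_collections <- function(zfish, human_ortho = NULL,
                              mode = c("all", "novel_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(zfish, "gene_set_collection"))
  if (is.null(human_ortho) || length(human_ortho) == 0L) return(zfish)
  stopifnot(inherits(human_ortho, "gene_set_collection"))
  if (human_ortho$namespace != zfish$namespace ||
      human_ortho$organism != zfish$organism)
    stop("collections must share namespace and organism; orthologize the ",
         "human collection first", call. = FALSE)
  keep <- if (mode == "all") {
    rep(TRUE, length(human_ortho))
  } else {
    !(counterpart_key(human_ortho$ids) %in% counterpart_key(zfish$ids))
  }
  if (!any(keep)) return(zfish)
  gene_set_collection(
    ids = c(zfish$ids, human_ortho$ids[keep]),
    set_names = c(zfish$set_names, human_ortho$set_names[keep]),
    members = c(zfish$members, human_ortho$members[keep]),
    source_db = c(zfish$source_db, human_ortho$source_db[keep]),
    annotation_organism = c(zfish$annotation_organism,
                            human_ortho$annotation_organism[keep]),
    namespace = zfish$namespace,
    organism = zfish$organism)
}
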