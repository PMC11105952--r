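#' @title Gene identifier namespaces
#' @description The four gene-ID namespaces supported throughout the package:
#'   NCBI Entrez Gene IDs, Ensembl gene IDs, ZFIN IDs and official gene
#'   symbols. Namespace arguments are matched case-insensitively against
#'   these names.
#' @format Character vector of length four.
#' @export
GENE_NAMESPACES <- c("ncbi", "ensembl", "zfin", "symbol")

# normalize a user-supplied namespace string; errors name the valid options
match_namespace <- function(ns, arg = "namespace") {
  if (length(ns) != 1L || is.na(ns) || !is.character(ns))
    stop(sprintf("'%s' must be a single string", arg), call. = FALSE)
  ns <- tolower(trimws(ns))
  if (!ns %in% GENE_NAMESPACES)
    stop(sprintf("unsupported %s '%s'; valid namespaces are: %s",
                 arg, ns, paste(GENE_NAMESPACES, collapse = ", ")),
         call. = FALSE)
  ns
}

trim_ids <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x)] <- NA_character_
  x
}

#' Construct a multi-namespace gene-ID mapping table
#'
#' A mapping table holds one row per gene with its identifier in any subset
#' of the supported namespaces (\code{\link{GENE_NAMESPACES}}). Rows with no
#' populated field are dropped and exact duplicate rows are collapsed; both
#' are counted in the load report attached as the \code{"load_report"}
#' attribute.
#'
#' @param df data.frame whose column names are a subset of the supported
#'   namespaces (case-insensitive). Empty strings and \code{NA} mean absent.
#' @return A \code{mapping_table}: a data.frame with one column per
#'   namespace present, plus a \code{load_report} attribute
#'   (\code{n_input}, \code{n_dropped_empty}, \code{n_dropped_duplicate},
#'   \code{n_rows}).
#' @seealso \code{\link{read_mapping_table}}, \code{\link{convert_ids}}
#' @export
mapping_table <- function(df) {
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  keep <- intersect(GENE_NAMESPACES, names(df))
  if (length(keep) == 0L)
    stop("no recognized namespace columns; expected a subset of: ",
         paste(GENE_NAMESPACES, collapse = ", "), call. = FALSE)
  df <- df[, keep, drop = FALSE]
  for (j in seq_along(df)) df[[j]] <- trim_ids(df[[j]])
  n_input <- nrow(df)
  nonempty <- rowSums(!is.na(as.matrix(df))) > 0L
  df <- df[nonempty, , drop = FALSE]
  n_empty <- n_input - nrow(df)
  key <- do.call(paste, c(lapply(df, function(x) ifelse(is.na(x), "", x)),
                          sep = "\r"))
  dup <- duplicated(key)
  df <- df[!dup, , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            class = c("mapping_table", "data.frame"),
            load_report = list(n_input = n_input,
                               n_dropped_empty = n_empty,
                               n_dropped_duplicate = sum(dup),
                               n_rows = nrow(df)))
}

#' Read a gene-ID mapping table from TSV
#'
#' The file must have a header row naming the namespaces present
#' (any subset of \code{ncbi}, \code{ensembl}, \code{zfin}, \code{symbol},
#' case-insensitive); empty cells mean the identifier is absent in that
#' namespace. Invalid rows (all-empty, exact duplicates) are dropped and
#' counted in the load report.
#'
#' @param path path to a tab-separated file with a header row.
#' @return A \code{\link{mapping_table}}.
#' @export
read_mapping_table <- function(path) {
  if (!file.exists(path)) stop("mapping table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", na.strings = c("", "NA"),
                          check.names = FALSE, quote = "",
                          comment.char = "#")
  mapping_table(df)
}

#' Convert gene identifiers between namespaces
#'
#' Joins the input identifiers to the mapping table on the source namespace
#' and emits the corresponding identifiers in the target namespace. Matching
#' is exact string match after whitespace trimming; symbols are matched
#' case-sensitively unless \code{case_insensitive = TRUE} (zebrafish symbols
#' are conventionally lower case, and silent case-folding can create false
#' merges). Inputs with several targets emit all of them (one mapped pair
#' per target); inputs with none are reported as unmapped, never silently
#' dropped.
#'
#' @param ids character vector of identifiers in \code{from_ns}.
#' @param from_ns,to_ns source and target namespaces (see
#'   \code{\link{GENE_NAMESPACES}}).
#' @param table a \code{\link{mapping_table}} covering both namespaces.
#' @param case_insensitive match ignoring case (intended for symbols).
#' @param keep_unmapped also emit unmapped inputs as mapped rows with an
#'   \code{NA} output (handy when writing a conversion table that must
#'   retain every input); they are still listed in \code{unmapped}.
#' @return A \code{conversion_result}: list with \code{mapped} (data.frame
#'   \code{input}, \code{output}, in order of first appearance of each
#'   input), \code{unmapped} (character), and \code{one_to_many_count}
#'   (number of inputs with more than one target).
#' @examples
#' mt <- mapping_table(data.frame(zfin = c("ZDB-1", "ZDB-2"),
#'                                ncbi = c("100", "200")))
#' convert_ids(c("ZDB-1", "ZDB-9"), "zfin", "ncbi", mt)
#' @export
convert_ids <- function(ids, from_ns, to_ns, table, case_insensitive = FALSE,
                        keep_unmapped = FALSE) {
  from_ns <- match_namespace(from_ns, "from_ns")
  to_ns <- match_namespace(to_ns, "to_ns")
  ids <- trim_ids(ids)
  ids <- ids[!is.na(ids)]
  ids <- ids[!duplicated(ids)]
  if (from_ns == to_ns)
    return(conversion_result(
      mapped = data.frame(input = ids, output = ids,
                          stringsAsFactors = FALSE),
      unmapped = character(0), one_to_many_count = 0L))
  if (!inherits(table, "mapping_table"))
    stop("'table' must be a mapping_table", call. = FALSE)
  for (ns in c(from_ns, to_ns))
    if (!ns %in% names(table))
      stop("mapping table has no '", ns, "' column", call. = FALSE)
  src <- table[[from_ns]]
  dst <- table[[to_ns]]
  key <- if (case_insensitive) tolower(src) else src
  lookup <- if (case_insensitive) tolower(ids) else ids
  pairs_in <- character(0); pairs_out <- character(0)
  unmapped <- character(0); one_to_many <- 0L
  for (i in seq_along(ids)) {
    hits <- dst[!is.na(key) & key == lookup[i] & !is.na(dst)]
    hits <- unique(hits)
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, ids[i])
    } else {
      if (length(hits) > 1L) one_to_many <- one_to_many + 1L
      pairs_in <- c(pairs_in, rep(ids[i], length(hits)))
      pairs_out <- c(pairs_out, hits)
    }
  }
  mapped <- data.frame(input = pairs_in, output = pairs_out,
                       stringsAsFactors = FALSE)
  if (keep_unmapped && length(unmapped))
    mapped <- rbind(mapped,
                    data.frame(input = unmapped, output = NA_character_,
                               stringsAsFactors = FALSE))
  conversion_result(mapped = mapped, unmapped = unmapped,
                    one_to_many_count = one_to_many)
}

conversion_result <- function(mapped, unmapped, one_to_many_count) {
  structure(list(mapped = mapped, unmapped = unmapped,
                 one_to_many_count = as.integer(one_to_many_count)),
            class = "conversion_result")
}

#' @export
print.conversion_result <- function(x, ...) {
  cat("Gene-ID conversion result\n")
  cat("  mapped inputs:   ",
      length(unique(x$mapped$input)), " (", nrow(x$mapped), " pairs, ",
      x$one_to_many_count, " one-to-many)\n", sep = "")
  cat("  unmapped inputs: ", length(x$unmapped), "\n", sep = "")
  if (length(x$unmapped))
    cat("    ", paste(utils::head(x$unmapped, 5), collapse = ", "),
        if (length(x$unmapped) > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Construct a zebrafish/human orthology table
#'
#' Orthology between zebrafish and human is many-to-many in both
#' directions: the teleost whole-genome duplication means one human gene
#' often has two zebrafish co-orthologs, and conversely. The table stores
#' unique (zebrafish, human) gene-ID pairs together with the namespace each
#' column is declared in.
#'
#' @param zfish_id,human_id character vectors of equal length.
#' @param zfish_ns,human_ns declared namespaces of the two columns.
#' @return An \code{orthology_table}: data.frame with columns
#'   \code{zfish_id}, \code{human_id} and namespace attributes.
#' @export
orthology_table <- function(zfish_id, human_id,
                            zfish_ns = "ncbi", human_ns = "ncbi") {
  zfish_id <- trim_ids(zfish_id)
  human_id <- trim_ids(human_id)
  if (length(zfish_id) != length(human_id))
    stop("zfish_id and human_id must have equal length", call. = FALSE)
  ok <- !is.na(zfish_id) & !is.na(human_id)
  df <- data.frame(zfish_id = zfish_id[ok], human_id = human_id[ok],
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("orthology_table", "data.frame"),
            zfish_ns = match_namespace(zfish_ns, "zfish_ns"),
            human_ns = match_namespace(human_ns, "human_ns"))
}

#' Read an orthology table from TSV
#'
#' Expects a header \code{zfish_id<TAB>human_id}. An optional metadata line
#' \code{#ns zfish=<ns> human=<ns>} before the header declares the
#' namespaces (default \code{ncbi} for both).
#'
#' @param path path to the tab-separated file.
#' @return An \code{\link{orthology_table}}.
#' @export
read_orthology <- function(path) {
  if (!file.exists(path)) stop("orthology file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  zns <- "ncbi"; hns <- "ncbi"
  meta <- grep("^#ns\\b", lines, value = TRUE)
  if (length(meta)) {
    m <- regmatches(meta[1],
                    regexec("zfish=([A-Za-z]+).*human=([A-Za-z]+)", meta[1]))[[1]]
    if (length(m) == 3L) { zns <- m[2]; hns <- m[3] }
  }
  lines <- lines[!startsWith(lines, "#")]
  df <- utils::read.delim(text = paste(lines, collapse = "\n"),
                          header = TRUE, sep = "\t",
                          colClasses = "character", quote = "")
  if (!all(c("zfish_id", "human_id") %in% names(df)))
    stop("orthology TSV must have header 'zfish_id<TAB>human_id'",
         call. = FALSE)
  orthology_table(df$zfish_id, df$human_id, zns, hns)
}

#' Write an orthology table to TSV
#'
#' Inverse of \code{\link{read_orthology}}; emits the namespace metadata
#' line followed by the two-column table.
#' @param ortho an \code{\link{orthology_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_orthology <- function(ortho, path) {
  stopifnot(inherits(ortho, "orthology_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#ns zfish=%s human=%s",
                     attr(ortho, "zfish_ns"), attr(ortho, "human_ns")), con)
  writeLines("zfish_id\thuman_id", con)
  if (nrow(ortho))
    writeLines(paste(ortho$zfish_id, ortho$human_id, sep = "\t"), con)
  invisible(path)
}

# shared expansion used by to_human / to_zebrafish
orthology_expand <- function(ids, from_col, to_col, ortho) {
  if (!inherits(ortho, "orthology_table"))
    stop("'ortho' must be an orthology_table", call. = FALSE)
  ids <- trim_ids(ids)
  ids <- ids[!is.na(ids)]
  ids <- ids[!duplicated(ids)]
  src <- ortho[[from_col]]
  dst <- ortho[[to_col]]
  pairs_in <- character(0); pairs_out <- character(0)
  unmapped <- character(0); one_to_many <- 0L
  for (i in seq_along(ids)) {
    hits <- unique(dst[src == ids[i]])
    if (length(hits) == 0L) {
      unmapped <- c(unmapped, ids[i])
    } else {
      if (length(hits) > 1L) one_to_many <- one_to_many + 1L
      pairs_in <- c(pairs_in, rep(ids[i], length(hits)))
      pairs_out <- c(pairs_out, hits)
    }
  }
  conversion_result(
    mapped = data.frame(input = pairs_in, output = pairs_out,
                        stringsAsFactors = FALSE),
    unmapped = unmapped, one_to_many_count = one_to_many)
}

#' Map zebrafish genes to their human orthologs
#'
#' Each zebrafish gene maps to \emph{all} of its human orthologs
#' (many-to-many expansion); genes absent from the orthology table are
#' reported as unmapped. No identifier is ever invented: every output
#' appears in the table.
#'
#' @param ids zebrafish gene IDs in the table's declared zebrafish
#'   namespace.
#' @param ortho an \code{\link{orthology_table}}.
#' @return A \code{conversion_result} (see \code{\link{convert_ids}}).
#' @export
to_human <- function(ids, ortho)
  orthology_expand(ids, "zfish_id", "human_id", ortho)

#' Map human genes to their zebrafish orthologs
#'
#' Mirror of \code{\link{to_human}}: each human gene expands to all its
#' zebrafish co-orthologs (often two, from the teleost whole-genome
#' duplication).
#'
#' @inheritParams to_human
#' @param ids human gene IDs in the table's declared human namespace.
#' @return A \code{conversion_result}.
#' @export
to_zebrafish <- function(ids, ortho)
  orthology_expand(ids, "human_id", "zfish_id", ortho)

#' Orthology coverage percentage
#'
#' Fraction (as a percentage) of a gene universe with at least one ortholog.
#' Either give an orthology table plus the universe of human genes, or give
#' the two counts directly (e.g. from a genome build report: protein-coding
#' genes and how many of them have a zebrafish ortholog).
#'
#' @param ortho an \code{\link{orthology_table}} (ignored when counts are
#'   given).
#' @param universe character vector of human gene IDs defining the
#'   denominator.
#' @param n_with_ortholog,n_total direct counts; when both are supplied the
#'   percentage is \code{100 * n_with_ortholog / n_total}.
#' @return Numeric percentage in [0, 100].
#' @export
orthology_coverage <- function(ortho = NULL, universe = NULL,
                               n_with_ortholog = NULL, n_total = NULL) {
  if (!is.null(n_with_ortholog) && !is.null(n_total)) {
    stopifnot(n_total > 0, n_with_ortholog >= 0, n_with_ortholog <= n_total)
    return(100 * n_with_ortholog / n_total)
  }
  stopifnot(inherits(ortho, "orthology_table"), length(universe) > 0)
  universe <- unique(trim_ids(universe))
  universe <- universe[!is.na(universe)]
  100 * mean(universe %in% ortho$human_id)
}
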