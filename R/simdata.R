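# Independent substreams per artifact: one user-facing seed drives a small
# family of derived seeds, so e.g. changing n_sets never perturbs the
# gene-level draws. Derived seeds stay below 2^31 for any integer input.
stream_seed <- function(seed, stream) {
  (abs(as.integer(seed)) %% 200000000L) * 10L + as.integer(stream)
}

with_stream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(stream_seed(seed, stream))
  expr
}

#' Configuration for the synthetic-data generators
#'
#' Describes a synthetic zebrafish/human study: genome sizes, the
#' orthology structure (a human gene has no zebrafish ortholog with
#' probability \code{p_no_ortholog}, two co-orthologs — the teleost
#' whole-genome-duplication signature — with probability
#' \code{p_two_orthologs}, otherwise one), a gene-set collection, and
#' optional planted enrichment signal. Defaults describe the package's
#' reference study conditions: a 2000-gene universe, 200 sets of 10-100
#' genes, 35\% of human genes without a zebrafish ortholog and 30\% with a
#' duplicated pair, and no planted signal (a null study).
#'
#' @param n_zfish_genes,n_human_genes genome sizes.
#' @param p_no_ortholog,p_two_orthologs orthology mixture probabilities;
#'   must sum to at most 1.
#' @param n_sets number of gene sets.
#' @param set_size_range integer pair: inclusive range of set sizes.
#' @param planted_sets \code{NULL} (null study) or a data.frame with
#'   columns \code{set_id}, \code{effect} (Beta shape in (0, 1]; smaller
#'   is stronger signal, 1 is null) and \code{direction} (\code{"up"} or
#'   \code{"down"}).
#' @param seed single integer driving every generator.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_zfish_genes = 2000L, n_human_genes = 2000L,
                       p_no_ortholog = 0.35, p_two_orthologs = 0.30,
                       n_sets = 200L, set_size_range = c(10L, 100L),
                       planted_sets = NULL, seed = 1L) {
  stopifnot(n_zfish_genes >= 1, n_human_genes >= 1, n_sets >= 1,
            p_no_ortholog >= 0, p_no_ortholog <= 1,
            p_two_orthologs >= 0, p_two_orthologs <= 1,
            p_no_ortholog + p_two_orthologs <= 1,
            length(set_size_range) == 2L,
            set_size_range[1] >= 1,
            set_size_range[1] <= set_size_range[2])
  if (!is.null(planted_sets)) {
    stopifnot(is.data.frame(planted_sets),
              all(c("set_id", "effect", "direction") %in%
                    names(planted_sets)),
              all(planted_sets$effect > 0 & planted_sets$effect <= 1),
              all(tolower(planted_sets$direction) %in% c("up", "down")))
    planted_sets$direction <- tolower(planted_sets$direction)
  }
  structure(list(n_zfish_genes = as.integer(n_zfish_genes),
                 n_human_genes = as.integer(n_human_genes),
                 p_no_ortholog = p_no_ortholog,
                 p_two_orthologs = p_two_orthologs,
                 n_sets = as.integer(n_sets),
                 set_size_range = as.integer(set_size_range),
                 planted_sets = planted_sets,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a bijective four-namespace mapping table
#'
#' One synthetic zebrafish gene per row with a distinct identifier in each
#' of the four supported namespaces (NCBI-, Ensembl-, ZFIN- and
#' symbol-styled). The table is bijective, so every conversion round-trip
#' is the identity on the full universe. Deterministic given the config.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A \code{\link{mapping_table}} of \code{n_zfish_genes} rows.
#' @export
gen_mapping_table <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  i <- seq_len(cfg$n_zfish_genes)
  mapping_table(data.frame(
    ncbi = sprintf("%d", 100000L + i),
    ensembl = sprintf("ENSDARG%011d", i),
    zfin = sprintf("ZDB-GENE-%06d", i),
    symbol = sprintf("gene%05d", i),
    stringsAsFactors = FALSE))
}

#' Generate a duplication-aware orthology table
#'
#' Each synthetic human gene independently receives 0 zebrafish orthologs
#' with probability \code{p_no_ortholog}, 2 distinct co-orthologs with
#' probability \code{p_two_orthologs} (mimicking retained teleost
#' whole-genome-duplication paralog pairs), and otherwise 1. Zebrafish
#' partners are drawn uniformly from the symbol universe of
#' \code{\link{gen_mapping_table}}, so the relation is many-to-many in
#' both directions. Deterministic given config and seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return An \code{\link{orthology_table}} in symbol namespaces, with
#'   human IDs \code{HUM00001...}.
#' @export
gen_orthology <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  human <- sprintf("HUM%05d", seq_len(cfg$n_human_genes))
  zfish_pool <- sprintf("gene%05d", seq_len(cfg$n_zfish_genes))
  with_stream(cfg$seed, 2L, {
    u <- stats::runif(cfg$n_human_genes)
    k <- ifelse(u < cfg$p_no_ortholog, 0L,
                ifelse(u < cfg$p_no_ortholog + cfg$p_two_orthologs, 2L, 1L))
    zz <- vector("list", cfg$n_human_genes)
    for (i in which(k > 0L))
      zz[[i]] <- sample(zfish_pool, k[i], replace = FALSE)
    orthology_table(zfish_id = unlist(zz),
                    human_id = rep(human, k),
                    zfish_ns = "symbol", human_ns = "symbol")
  })
}

#' Generate a synthetic gene-set collection
#'
#' \code{n_sets} sets with sizes drawn uniformly from
#' \code{set_size_range} and members sampled without replacement from the
#' given universe; ids are KEGG-pathway-styled (\code{dre00001}, ...).
#' Deterministic given config and seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param universe character vector of gene IDs to sample members from.
#' @return A \code{\link{gene_set_collection}} (symbol namespace,
#'   zebrafish).
#' @export
gen_collection <- function(cfg, universe) {
  stopifnot(inherits(cfg, "sim_config"), length(universe) >= 1)
  universe <- unique(as.character(universe))
  hi <- min(cfg$set_size_range[2], length(universe))
  lo <- min(cfg$set_size_range[1], hi)
  with_stream(cfg$seed, 3L, {
    sizes <- lo + sample.int(hi - lo + 1L, cfg$n_sets, replace = TRUE) - 1L
    members <- lapply(sizes, function(s) sample(universe, s))
    gene_set_collection(
      ids = sprintf("dre%05d", seq_len(cfg$n_sets)),
      set_names = sprintf("synthetic pathway %d", seq_len(cfg$n_sets)),
      members = members,
      source_db = "KEGG_PATHWAY", annotation_organism = "ZEBRAFISH",
      namespace = "symbol", organism = "zebrafish")
  })
}

#' Generate a DE table with optional planted enrichment
#'
#' Background genes draw their p-value from Uniform(0, 1) and their fold
#' change from a standard normal whose sign is a fair coin — a global null.
#' Genes belonging to a planted set instead draw
#' \eqn{p \sim \mathrm{Beta}(a, 1)} with shape \eqn{a \in (0, 1]}
#' (stochastically small for \eqn{a < 1}; \eqn{a = 1} recovers the null),
#' and their fold-change sign matches the planted direction with
#' probability 0.9. When planted sets overlap, later plantings override
#' earlier ones for the shared genes (recorded in the
#' \code{"overridden"} attribute). Deterministic given config and seed;
#' an optional \code{rep_seed} replaces the config seed for replicate
#' draws.
#'
#' @param cfg a \code{\link{sim_config}} (its \code{planted_sets} plant
#'   the signal).
#' @param universe character vector of gene IDs.
#' @param collection the \code{\link{gene_set_collection}} the planted
#'   set ids refer to.
#' @param rep_seed optional integer overriding \code{cfg$seed} for this
#'   draw.
#' @return A \code{\link{de_table}} over the universe.
#' @export
gen_de_table <- function(cfg, universe, collection = NULL,
                         rep_seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  universe <- unique(as.character(universe))
  n <- length(universe)
  planted <- cfg$planted_sets
  if (!is.null(planted) && nrow(planted)) {
    stopifnot(inherits(collection, "gene_set_collection"))
    missing_ids <- setdiff(planted$set_id, collection$ids)
    if (length(missing_ids))
      stop("planted set ids not in collection: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(rep_seed)) cfg$seed else as.integer(rep_seed)
  with_stream(seed, 4L, {
    p <- stats::runif(n)
    sgn <- ifelse(stats::runif(n) < 0.5, -1, 1)
    lfc <- sgn * abs(stats::rnorm(n))
    overridden <- character(0)
    assigned <- rep(FALSE, n)
    if (!is.null(planted) && nrow(planted)) {
      for (j in seq_len(nrow(planted))) {
        idx <- which(universe %in%
                       collection$members[[match(planted$set_id[j],
                                                 collection$ids)]])
        overridden <- c(overridden, universe[idx][assigned[idx]])
        a <- planted$effect[j]
        # Beta(a, 1) via inverse CDF: U^(1/a)
        p[idx] <- stats::runif(length(idx))^(1 / a)
        want <- if (planted$direction[j] == "up") 1 else -1
        match_dir <- stats::runif(length(idx)) < 0.9
        lfc[idx] <- ifelse(match_dir, want, -want) * abs(stats::rnorm(length(idx)))
        assigned[idx] <- TRUE
      }
    }
    out <- de_table(universe, p, lfc)
    attr(out, "overridden") <- unique(overridden)
    out
  })
}

#' Null-calibration and power study of the enrichment tests
#'
#' Repeatedly generates a DE table under the config's conditions and runs
#' \code{\link{enrich_collection}}, measuring the type-I error rate (the
#' fraction of non-planted set tests with raw p below \code{alpha}) and,
#' per planted set, the power (fraction of replicates detected at raw
#' p < \code{alpha}). With \code{direction = "both"} it additionally
#' records, per planted set, how often a detection carried the planted
#' direction (the direction whose test has the smaller p-value).
#'
#' The Monte-Carlo standard error of the type-I rate is estimated from the
#' per-replicate rejection fractions (sd across replicates /
#' \eqn{\sqrt{reps}}), which respects the dependence among the set tests
#' within one replicate.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param method \code{"fisher"} or \code{"logistic"}.
#' @param alpha nominal level for raw-p rejection (default 0.05).
#' @param reps number of Monte-Carlo replicates; below 50 a warning is
#'   issued (Monte-Carlo error too large to interpret).
#' @param direction passed to \code{\link{enrich_collection}}.
#' @param sig_threshold Fisher classification cut-off.
#' @return A \code{calibration_result} list: \code{type_I_rate},
#'   \code{type_I_se}, \code{power} (named by planted set),
#'   \code{direction_recovery} (named, \code{NA} unless
#'   \code{direction = "both"} and detections occurred), \code{reps},
#'   \code{alpha}, \code{method}.
#' @export
calibration_run <- function(cfg, method = "fisher", alpha = 0.05,
                            reps = 100L, direction = "nondirectional",
                            sig_threshold = 0.05) {
  stopifnot(inherits(cfg, "sim_config"))
  reps <- as.integer(reps)
  if (reps < 50L)
    warning("fewer than 50 replicates: Monte-Carlo error will be large",
            call. = FALSE)
  universe <- gen_mapping_table(cfg)$symbol
  coll <- gen_collection(cfg, universe)
  planted_ids <- if (is.null(cfg$planted_sets)) character(0) else
    cfg$planted_sets$set_id
  rep_seeds <- with_stream(cfg$seed, 5L, sample.int(1e9L, reps))
  null_frac <- numeric(reps)
  det <- matrix(0L, nrow = reps, ncol = length(planted_ids),
                dimnames = list(NULL, planted_ids))
  dir_ok <- matrix(NA, nrow = reps, ncol = length(planted_ids),
                   dimnames = list(NULL, planted_ids))
  for (r in seq_len(reps)) {
    de <- gen_de_table(cfg, universe, coll, rep_seed = rep_seeds[r])
    res <- enrich_collection(de, coll, method = method,
                             direction = direction,
                             sig_threshold = sig_threshold,
                             correction = "none")
    df <- as.data.frame(res)
    is_null <- !(df$set_id %in% planted_ids)
    null_frac[r] <- mean(df$pvalue[is_null] < alpha)
    for (j in seq_along(planted_ids)) {
      rows <- df[df$set_id == planted_ids[j], , drop = FALSE]
      # detection means evidence of enrichment: for the logistic method the
      # Wald p is two-sided, so a rejection only counts with beta > 0
      # (beta < 0 is significant depletion of evidence, not enrichment)
      if (method == "logistic") rows <- rows[rows$effect > 0, , drop = FALSE]
      if (!nrow(rows)) next
      det[r, j] <- as.integer(min(rows$pvalue) < alpha)
      if (direction == "both" && det[r, j] == 1L) {
        best <- rows$direction[which.min(rows$pvalue)]
        dir_ok[r, j] <- tolower(best) == cfg$planted_sets$direction[j]
      }
    }
  }
  structure(list(
    type_I_rate = mean(null_frac),
    type_I_se = stats::sd(null_frac) / sqrt(reps),
    power = if (length(planted_ids)) colMeans(det) else numeric(0),
    direction_recovery = if (length(planted_ids))
      apply(dir_ok, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v)) mean(v) else NA_real_
      }) else numeric(0),
    reps = reps, alpha = alpha, method = method,
    direction = direction), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration (%s, %d reps): type-I rate %.4f (MC se %.4f) at alpha %g\n",
              x$method, x$reps, x$type_I_rate, x$type_I_se, x$alpha))
  if (length(x$power)) {
    cat("  power:\n")
    for (id in names(x$power))
      cat(sprintf("    %s: %.3f%s\n", id, x$power[[id]],
                  if (!is.na(x$direction_recovery[[id]]))
                    sprintf(" (direction recovery %.3f)",
                            x$direction_recovery[[id]]) else ""))
  }
  invisible(x)
}

#' Choose equal-size sets for a power study
#'
#' Power comparisons across planted effect strengths are only meaningful
#' at a fixed set size (power grows with set size). This picks \code{k}
#' sets of one common size — the size with enough sets whose median
#' member count is closest to the collection's median — so effects can be
#' planted on a like-for-like basis.
#'
#' @param collection a \code{\link{gene_set_collection}}.
#' @param k how many sets to return.
#' @return Character vector of \code{k} set ids, all with the same number
#'   of members.
#' @export
equal_size_sets <- function(collection, k = 3L) {
  stopifnot(inherits(collection, "gene_set_collection"), k >= 1)
  sizes <- lengths(collection$members)
  tab <- table(sizes)
  ok <- as.integer(names(tab))[tab >= k]
  if (!length(ok))
    stop("no set size occurs ", k, " times in the collection",
         call. = FALSE)
  target <- ok[which.min(abs(ok - stats::median(sizes)))]
  collection$ids[sizes == target][seq_len(k)]
}

#' Write a full synthetic study to disk
#'
#' Emits \code{map.tsv}, \code{ortho.tsv}, \code{sets.gmt} and
#' \code{de.tsv} for a config, plus a \code{manifest.txt} recording the
#' configuration and seed so any fixture set is exactly reproducible.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param outdir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_sim_study <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  map <- gen_mapping_table(cfg)
  ortho <- gen_orthology(cfg)
  coll <- gen_collection(cfg, map$symbol)
  de <- gen_de_table(cfg, map$symbol, coll)
  files <- c(map = file.path(outdir, "map.tsv"),
             ortho = file.path(outdir, "ortho.tsv"),
             sets = file.path(outdir, "sets.gmt"),
             de = file.path(outdir, "de.tsv"),
             manifest = file.path(outdir, "manifest.txt"))
  utils::write.table(map, files[["map"]], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  write_orthology(ortho, files[["ortho"]])
  write_gmt(coll, files[["sets"]])
  write_de_table(de, files[["de"]])
  writeLines(c("synthetic study manifest",
               utils::capture.output(utils::str(unclass(cfg)))),
             files[["manifest"]])
  invisible(files)
}
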