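#' Construct a differential-expression table
#'
#' Per-gene differential-expression evidence: a p-value and a signed log2
#' fold change. The deduplicated gene list defines the background universe
#' for all enrichment tests. Duplicate genes are collapsed to their minimum
#' p-value (keeping that record's fold change); p-values of exactly 0 are
#' clamped to 1e-300 so that \code{-log(p)} stays finite.
#'
#' @param gene character vector of gene IDs.
#' @param pvalue numeric vector of DE p-values in (0, 1] (0 is clamped).
#' @param log2fc numeric vector of signed log2 fold changes.
#' @return A \code{de_table}: data.frame with columns \code{gene},
#'   \code{pvalue}, \code{log2fc}, one row per gene, plus an
#'   \code{"n_collapsed"} attribute counting collapsed duplicates.
#' @export
de_table <- function(gene, pvalue, log2fc = 0) {
  gene <- trim_ids(gene)
  pvalue <- as.numeric(pvalue)
  log2fc <- rep_len(as.numeric(log2fc), length(gene))
  ok <- !is.na(gene) & !is.na(pvalue)
  gene <- gene[ok]; pvalue <- pvalue[ok]; log2fc <- log2fc[ok]
  if (any(pvalue < 0 | pvalue > 1))
    stop("DE p-values must lie in [0, 1]", call. = FALSE)
  pvalue <- pmax(pvalue, 1e-300)
  o <- order(pvalue, method = "radix")
  gene <- gene[o]; pvalue <- pvalue[o]; log2fc <- log2fc[o]
  dup <- duplicated(gene)
  df <- data.frame(gene = gene[!dup], pvalue = pvalue[!dup],
                   log2fc = log2fc[!dup], stringsAsFactors = FALSE)
  df <- df[order(df$gene, method = "radix"), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) < 1L) stop("DE table is empty", call. = FALSE)
  structure(df, class = c("de_table", "data.frame"),
            n_collapsed = sum(dup))
}

#' Read a differential-expression table from TSV
#'
#' Expects a header with columns \code{gene}, \code{pvalue}, \code{log2fc}
#' (extra columns are ignored).
#'
#' @param path path to the tab-separated file.
#' @return A \code{\link{de_table}}.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stop("DE table file not found: ", path,
                               call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#")
  need <- c("gene", "pvalue", "log2fc")
  if (!all(need %in% names(df)))
    stop("DE TSV must have columns gene, pvalue, log2fc", call. = FALSE)
  de_table(df$gene, df$pvalue, df$log2fc)
}

#' Write a DE table to TSV
#' @param de a \code{\link{de_table}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(de, path) {
  stopifnot(inherits(de, "de_table"))
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

DIRECTIONS <- c("nondirectional", "up", "down")

# significance indicator under the (optional) directional rule:
# p < threshold, and the fold change must point the right way.
# log2fc == 0 counts as neither up- nor down-significant.
de_significant <- function(de, sig_threshold, direction) {
  sig <- de$pvalue < sig_threshold
  switch(direction,
         nondirectional = sig,
         up = sig & de$log2fc > 0,
         down = sig & de$log2fc < 0)
}

#' Build the 2x2 contingency table for one gene set
#'
#' Classifies every gene of the DE universe by set membership and by
#' significance (\code{pvalue < sig_threshold}, restricted to positive or
#' negative fold change for the directional variants):
#' \code{a} = in set and significant, \code{b} = not in set and
#' significant, \code{c} = in set and not significant, \code{d} = neither;
#' \code{a + b + c + d = N}, the universe size. Set membership is
#' restricted to genes present in the universe; a set with no gene in the
#' universe is flagged degenerate (and skipped by
#' \code{\link{enrich_collection}}).
#'
#' @param de a \code{\link{de_table}} defining the universe.
#' @param members character vector of the set's member genes (or a
#'   \code{gene_set_collection} set via \code{\link{genes_in_set}}).
#' @param sig_threshold significance cut-off on the raw DE p-value,
#'   in (0, 1); default 0.05.
#' @param direction \code{"nondirectional"}, \code{"up"} or \code{"down"}.
#' @return A \code{contingency_table}: list with integer fields \code{a},
#'   \code{b}, \code{c}, \code{d}, \code{N} and logical \code{degenerate}.
#' @examples
#' de <- de_table(c("g1", "g2", "g3", "g4"), c(0.01, 0.2, 0.03, 0.9))
#' build_contingency(de, c("g1", "g2"))   # a=1 b=1 c=1 d=1
#' @export
build_contingency <- function(de, members, sig_threshold = 0.05,
                              direction = "nondirectional") {
  stopifnot(inherits(de, "de_table"))
  direction <- match.arg(tolower(direction), DIRECTIONS)
  if (!(sig_threshold > 0 && sig_threshold < 1))
    stop("sig_threshold must lie strictly between 0 and 1", call. = FALSE)
  in_set <- de$gene %in% members
  sig <- de_significant(de, sig_threshold, direction)
  a <- sum(in_set & sig); c_ <- sum(in_set & !sig)
  b <- sum(!in_set & sig); d <- sum(!in_set & !sig)
  structure(list(a = as.integer(a), b = as.integer(b), c = as.integer(c_),
                 d = as.integer(d), N = as.integer(a + b + c_ + d),
                 degenerate = (a + c_) == 0L),
            class = "contingency_table")
}

#' Hypergeometric point probability of a contingency table
#'
#' The exact probability of observing the table under the hypergeometric
#' null with its margins fixed:
#' \deqn{p = \binom{a+b}{a}\binom{c+d}{d} / \binom{N}{a+c}.}
#' Computed in log space (\code{lchoose}) so it is stable for large
#' universes. A table with an empty margin admits only one configuration
#' and has probability 1.
#'
#' @param t a \code{\link{build_contingency}} table, or anything with
#'   fields \code{a}, \code{b}, \code{c}, \code{d} (e.g.
#'   \code{list(a=1, b=1, c=1, d=1)}).
#' @return The point probability, in (0, 1].
#' @examples
#' hypergeom_point_prob(list(a = 1, b = 1, c = 1, d = 1))  # 2/3
#' @export
hypergeom_point_prob <- function(t) {
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  exp(lchoose(a + b, a) + lchoose(c_ + d, d) - lchoose(a + b + c_ + d, a + c_))
}

# log point probabilities of every feasible table with the margins of t,
# indexed by a' over its support
log_hyper_support <- function(K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  a_vals <- lo:hi
  list(a = a_vals,
       logp = lchoose(K, a_vals) + lchoose(N - K, n - a_vals) -
              lchoose(N, n))
}

logsumexp <- function(x) {
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' One-sided Fisher exact p-value of a contingency table
#'
#' Tail probability of the hypergeometric null at the observed table's
#' fixed margins: \code{tail = "over"} sums the point probabilities of all
#' tables with \code{a' >= a} (overrepresentation of the set among
#' significant genes), \code{tail = "under"} of all with \code{a' <= a}
#' (depletion). Summation is done in log space over the exact support.
#'
#' @param t a \code{\link{build_contingency}} table (or a list with
#'   \code{a}, \code{b}, \code{c}, \code{d}).
#' @param tail \code{"over"} or \code{"under"}.
#' @return The one-sided p-value, in (0, 1].
#' @export
fisher_pvalue <- function(t, tail = c("over", "under")) {
  tail <- match.arg(tail)
  a <- t$a; b <- t$b; c_ <- t$c; d <- t$d
  stopifnot(a >= 0, b >= 0, c_ >= 0, d >= 0)
  K <- a + c_           # set size in universe
  n <- a + b            # significant genes
  N <- a + b + c_ + d
  sup <- log_hyper_support(K, n, N)
  sel <- if (tail == "over") sup$a >= a else sup$a <= a
  min(1, exp(logsumexp(sup$logp[sel])))
}

#' Fit the cut-off-free logistic enrichment model
#'
#' Fits, by iteratively reweighted least squares, the logistic regression
#' \deqn{\log\frac{p}{1-p} = \alpha + \beta x,}
#' where \eqn{p} is the probability that a gene belongs to the gene set and
#' the explanatory variable \eqn{x} is the negative natural log of the
#' gene's differential-expression p-value. Unlike overrepresentation
#' analysis, no significance cut-off is applied: every gene contributes
#' through the full continuum of its DE evidence, and \eqn{\beta > 0}
#' means set members tend to have stronger DE evidence (enrichment).
#'
#' Iteration stops when the relative change in log-likelihood falls below
#' \code{1e-12} (tight enough that the estimate is the maximum-likelihood
#' solution to near machine precision) or after 100 iterations. The standard error of
#' \eqn{\hat\beta} comes from the observed information matrix. Complete
#' separation (the fitted probabilities perfectly classify membership while
#' the slope diverges) is detected and reported via
#' \code{converged = FALSE} with a diagnostic, never returned as a
#' spuriously precise estimate.
#'
#' @param x numeric vector, typically \code{-log(pvalue)}.
#' @param membership binary (0/1 or logical) set-membership indicator;
#'   both classes must be present.
#' @return A \code{logistic_fit}: list with \code{alpha}, \code{beta},
#'   \code{se_beta}, \code{W} (Wald statistic \eqn{\hat\beta/s(\hat\beta)}),
#'   \code{pvalue}, \code{converged}, \code{n_iter}, \code{diagnostic}.
#' @seealso \code{\link{wald_test}}
#' @export
logistic_fit <- function(x, membership) {
  x <- as.numeric(x)
  y <- as.numeric(membership)
  if (length(x) != length(y) || length(x) < 2L)
    stop("x and membership must have equal length >= 2", call. = FALSE)
  if (anyNA(x) || anyNA(y) || !all(y %in% c(0, 1)))
    stop("membership must be binary with no missing values", call. = FALSE)
  if (length(unique(y)) < 2L)
    stop("membership has a single class; the model is not identifiable",
         call. = FALSE)

  # numerically safe Bernoulli log-likelihood
  loglik <- function(a, b) {
    eta <- a + b * x
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  alpha <- log(mean(y) / (1 - mean(y)))  # null start
  beta <- 0
  ll_old <- loglik(alpha, beta)
  diagnostic <- NA_character_
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    eta <- alpha + beta * x
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    Sw <- sum(w); Swx <- sum(w * x); Swxx <- sum(w * x * x)
    det <- Sw * Swxx - Swx * Swx
    if (det <= 1e-10 * Sw * (Swxx + 1)) {
      diagnostic <- "design is numerically singular (x nearly constant)"
      break
    }
    Swz <- sum(w * z); Swxz <- sum(w * x * z)
    # IRLS proposal, with step halving so the likelihood never decreases
    d_alpha <- (Swxx * Swz - Swx * Swxz) / det - alpha
    d_beta <- (Sw * Swxz - Swx * Swz) / det - beta
    step <- 1
    repeat {
      ll <- loglik(alpha + step * d_alpha, beta + step * d_beta)
      if (is.finite(ll) && ll >= ll_old - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    if (step < 1e-10) {
      mu <- stats::plogis(alpha + beta * x)
      diagnostic <- if (all(mu[y == 1] > 1 - 1e-8) &&
                        all(mu[y == 0] < 1e-8))
        "complete separation detected; slope is unbounded"
      else "IRLS step halving failed to improve the likelihood"
      break
    }
    alpha <- alpha + step * d_alpha
    beta <- beta + step * d_beta
    if (abs(ll - ll_old) < 1e-12 * (abs(ll_old) + 1e-8)) {
      # a diverging slope that perfectly classifies membership is
      # separation, not convergence
      mu <- stats::plogis(alpha + beta * x)
      if (abs(beta) > 1e3 && all(mu[y == 1] > 1 - 1e-8) &&
          all(mu[y == 0] < 1e-8)) {
        diagnostic <- "complete separation detected; slope is unbounded"
      } else {
        converged <- TRUE
      }
      break
    }
    ll_old <- ll
    if (iter >= 100L) {
      diagnostic <- "IRLS did not converge in 100 iterations"
      break
    }
  }
  se_beta <- NA_real_; W <- NA_real_; pv <- NA_real_
  if (converged) {
    mu <- stats::plogis(alpha + beta * x)
    w <- mu * (1 - mu)
    Sw <- sum(w); Swx <- sum(w * x); Swxx <- sum(w * x * x)
    det <- Sw * Swxx - Swx * Swx
    se_beta <- sqrt(Sw / det)
    W <- beta / se_beta
    pv <- max(stats::pchisq(W * W, df = 1, lower.tail = FALSE), 1e-300)
  }
  structure(list(alpha = alpha, beta = beta, se_beta = se_beta,
                 W = W, pvalue = pv, converged = converged,
                 n_iter = iter, diagnostic = diagnostic),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("Logistic enrichment fit",
      if (!x$converged) " (NOT converged)" else "", "\n", sep = "")
  cat(sprintf("  alpha = %.6g, beta = %.6g (se %.4g)\n",
              x$alpha, x$beta, x$se_beta))
  if (x$converged)
    cat(sprintf("  Wald W = %.4g, p = %.4g  [%d iterations]\n",
                x$W, x$pvalue, x$n_iter))
  if (!is.na(x$diagnostic)) cat("  ", x$diagnostic, "\n", sep = "")
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...)
  c(alpha = object$alpha, beta = object$beta)

#' Wald test of the logistic slope
#'
#' Tests whether the slope \eqn{\beta} of the logistic enrichment model
#' differs from zero: \eqn{W = \hat\beta / s(\hat\beta)}, with
#' \eqn{W^2} compared to a chi-square distribution with one degree of
#' freedom. A positive slope means the gene set is enriched (its members
#' carry stronger differential-expression evidence).
#'
#' @param fit a converged \code{\link{logistic_fit}}.
#' @return List with \code{W}, \code{pvalue}, and logical \code{enriched}
#'   (\code{beta > 0}).
#' @export
wald_test <- function(fit) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (!fit$converged)
    stop("logistic fit did not converge: ", fit$diagnostic, call. = FALSE)
  W <- fit$beta / fit$se_beta
  list(W = W,
       pvalue = max(stats::pchisq(W * W, df = 1, lower.tail = FALSE),
                    1e-300),
       enriched = fit$beta > 0)
}

#' Adjust p-values for multiple testing
#'
#' Benjamini-Hochberg step-up or Bonferroni, applied across exactly the
#' set of tests handed in; \code{"none"} returns the input. Output is
#' always elementwise at least the input and never exceeds 1.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param method \code{"BH"}, \code{"bonferroni"} or \code{"none"}
#'   (case-insensitive).
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjust_pvalues <- function(p, method = c("BH", "bonferroni", "none")) {
  method <- match.arg(tolower(method[1]),
                      c("bh", "bonferroni", "none"))
  if (!length(p)) return(numeric(0))
  stopifnot(all(p > 0 & p <= 1))
  stats::p.adjust(p, method = c(bh = "BH", bonferroni = "bonferroni",
                                none = "none")[[method]])
}

#' Percentage of significant genes within a set
#'
#' \code{100 * a / (a + c)} from the set's contingency table: the share of
#' universe members of the set that are significant at the cut-off (this
#' is the dot-size channel of \code{\link{dot_plot}}). Returns 0 for a set
#' with no gene in the universe.
#'
#' @inheritParams build_contingency
#' @return Percentage in [0, 100].
#' @export
pct_sig_genes <- function(de, members, sig_threshold = 0.05,
                          direction = "nondirectional") {
  t <- build_contingency(de, members, sig_threshold, direction)
  if (t$a + t$c == 0L) return(0)
  100 * t$a / (t$a + t$c)
}

# odds ratio of a 2x2 table; Haldane-Anscombe 0.5 correction only when a
# zero cell would make the ratio 0/undefined/infinite
odds_ratio <- function(t) {
  if (t$a == 0L || t$b == 0L || t$c == 0L || t$d == 0L)
    return(((t$a + 0.5) * (t$d + 0.5)) / ((t$b + 0.5) * (t$c + 0.5)))
  (t$a * t$d) / (t$b * t$c)
}

#' Enrichment analysis of a gene-set collection
#'
#' The package's central fitting function: tests every set of a collection
#' (or a chosen subset) against a differential-expression table, by either
#' Fisher's exact test on the 2x2 overrepresentation table or the
#' cut-off-free logistic regression with a Wald test. Directional variants
#' test up- or downregulation: Fisher restricts "significant" to the
#' matching fold-change sign, while the logistic model masks the evidence
#' variable, \code{x = -log(p)} for genes whose fold change has the tested
#' sign and \code{x = 0} otherwise. \code{direction = "both"} runs the up
#' and down tests and stacks the results.
#'
#' Sets with no member in the DE universe (and, for the logistic method,
#' sets covering the whole universe) are degenerate and skipped; their ids
#' are kept in the \code{"skipped"} attribute. P-values are adjusted across
#' exactly the tested sets, separately per direction. Rows are ordered by
#' p-value, ties broken by set id, so results are byte-stable.
#'
#' @param de a \code{\link{de_table}}.
#' @param coll a \code{\link{gene_set_collection}} in the same namespace
#'   as the DE gene IDs.
#' @param method \code{"fisher"} or \code{"logistic"}.
#' @param direction \code{"nondirectional"}, \code{"up"}, \code{"down"}
#'   or \code{"both"}.
#' @param sig_threshold raw-p significance cut-off used by the Fisher
#'   contingency classification and by \code{pct_sig_genes} (default
#'   0.05).
#' @param correction multiple-testing adjustment: \code{"BH"} (default),
#'   \code{"bonferroni"} or \code{"none"}.
#' @param subset_ids optional character vector restricting the analysis to
#'   these set ids.
#' @param tail Fisher tail: \code{"over"} (enrichment, default) or
#'   \code{"under"} (depletion).
#' @return An \code{enrichment_result}: data.frame with one row per tested
#'   set and columns \code{set_id}, \code{set_name},
#'   \code{annotation_organism}, \code{method}, \code{direction},
#'   \code{effect} (odds ratio for Fisher, slope beta for logistic),
#'   \code{statistic} (hypergeometric point probability, or Wald W),
#'   \code{pvalue}, \code{adj_pvalue}, \code{n_set_in_universe},
#'   \code{pct_sig_genes}, \code{source_db}; attributes record the call
#'   parameters and skipped sets.
#' @examples
#' cfg <- sim_config(n_zfish_genes = 300, n_sets = 10, seed = 7)
#' uni <- gen_mapping_table(cfg)$symbol
#' coll <- gen_collection(cfg, uni)
#' de <- gen_de_table(cfg, uni, coll)
#' enrich_collection(de, coll, method = "fisher")
#' @export
enrich_collection <- function(de, coll,
                              method = c("fisher", "logistic"),
                              direction = "nondirectional",
                              sig_threshold = 0.05,
                              correction = "BH",
                              subset_ids = NULL,
                              tail = "over") {
  stopifnot(inherits(de, "de_table"),
            inherits(coll, "gene_set_collection"))
  method <- match.arg(tolower(method[1]), c("fisher", "logistic"))
  direction <- match.arg(tolower(direction),
                         c(DIRECTIONS, "both"))
  if (!is.null(subset_ids)) {
    missing_ids <- setdiff(subset_ids, coll$ids)
    if (length(missing_ids))
      stop("subset_ids not in collection: ",
           paste(missing_ids, collapse = ", "), call. = FALSE)
    coll <- coll[match(subset_ids, coll$ids)]
  }
  dirs <- if (direction == "both") c("up", "down") else direction
  pieces <- list()
  skipped <- character(0)
  for (dir in dirs) {
    x <- if (method == "logistic") {
      xx <- -log(de$pvalue)
      if (dir == "up") xx[de$log2fc <= 0] <- 0
      if (dir == "down") xx[de$log2fc >= 0] <- 0
      xx
    }
    n <- length(coll)
    eff <- stat <- pv <- nset <- pct <- rep(NA_real_, n)
    keep <- rep(TRUE, n)
    for (i in seq_len(n)) {
      t <- build_contingency(de, coll$members[[i]], sig_threshold, dir)
      nset[i] <- t$a + t$c
      if (t$degenerate) { keep[i] <- FALSE; next }
      pct[i] <- if (nset[i] > 0) 100 * t$a / nset[i] else 0
      if (method == "fisher") {
        eff[i] <- odds_ratio(t)
        stat[i] <- hypergeom_point_prob(t)
        pv[i] <- fisher_pvalue(t, tail)
      } else {
        memb <- de$gene %in% coll$members[[i]]
        if (all(memb)) { keep[i] <- FALSE; next }
        fit <- logistic_fit(x, memb)
        if (!fit$converged) { keep[i] <- FALSE; next }
        wt <- wald_test(fit)
        eff[i] <- fit$beta
        stat[i] <- wt$W
        pv[i] <- wt$pvalue
      }
    }
    skipped <- c(skipped, coll$ids[!keep])
    if (!any(keep)) next
    adj <- adjust_pvalues(pv[keep], correction)
    pieces[[dir]] <- data.frame(
      set_id = coll$ids[keep],
      set_name = coll$set_names[keep],
      annotation_organism = coll$annotation_organism[keep],
      method = toupper(method),
      direction = toupper(dir),
      effect = eff[keep],
      statistic = stat[keep],
      pvalue = pv[keep],
      adj_pvalue = adj,
      n_set_in_universe = as.integer(nset[keep]),
      pct_sig_genes = pct[keep],
      source_db = coll$source_db[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(pieces))
    stop("no testable gene set (collection empty after subsetting and ",
         "degenerate-set filtering)", call. = FALSE)
  out <- do.call(rbind, pieces)
  out <- out[order(out$pvalue, out$set_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("enrichment_result", "data.frame"),
            method = toupper(method), direction = toupper(direction),
            sig_threshold = sig_threshold, correction = correction,
            universe_size = nrow(de), skipped = unique(skipped))
}

#' @export
print.enrichment_result <- function(x, n = 10L, ...) {
  cat(sprintf("Gene-set enrichment (%s, direction %s): %d tests over a %d-gene universe\n",
              attr(x, "method"), attr(x, "direction"), nrow(x),
              attr(x, "universe_size")))
  sk <- attr(x, "skipped")
  if (length(sk)) cat("  skipped (degenerate):", length(sk), "sets\n")
  df <- as.data.frame(x)
  df <- df[, c("set_id", "direction", "effect", "pvalue", "adj_pvalue",
               "n_set_in_universe", "pct_sig_genes")]
  print(utils::head(df, n), digits = 4)
  if (nrow(x) > n) cat("  ...", nrow(x) - n, "more rows\n")
  invisible(x)
}

#' @export
summary.enrichment_result <- function(object, alpha = 0.05, ...) {
  df <- as.data.frame(object)
  sig <- df$adj_pvalue < alpha
  out <- list(method = attr(object, "method"),
              direction = attr(object, "direction"),
              n_tested = nrow(df),
              alpha = alpha,
              n_significant = sum(sig),
              by_direction = table(df$direction[sig]),
              by_annotation = table(df$annotation_organism[sig]),
              top = utils::head(df[, c("set_id", "direction", "effect",
                                       "pvalue", "adj_pvalue")], 5))
  class(out) <- "summary.enrichment_result"
  out
}

#' @export
print.summary.enrichment_result <- function(x, ...) {
  cat(sprintf("%s enrichment, %d sets tested, %d significant at adjusted p < %g\n",
              x$method, x$n_tested, x$n_significant, x$alpha))
  if (x$n_significant) {
    cat("  by direction: ",
        paste(sprintf("%s=%d", names(x$by_direction),
                      as.integer(x$by_direction)), collapse = ", "), "\n")
    cat("  by annotation:",
        paste(sprintf("%s=%d", names(x$by_annotation),
                      as.integer(x$by_annotation)), collapse = ", "), "\n")
    cat("  top sets:\n")
    print(x$top, digits = 4)
  }
  invisible(x)
}

#' Write an enrichment result to TSV or JSON
#'
#' @param res an \code{enrichment_result}.
#' @param path output file; a \code{.json} extension (or
#'   \code{format = "json"}) selects JSON (requires jsonlite), anything
#'   else tab-separated text.
#' @param format \code{"tsv"} or \code{"json"}; default inferred from
#'   \code{path}.
#' @return \code{path}, invisibly.
#' @export
write_enrichment <- function(res, path, format = NULL) {
  stopifnot(inherits(res, "enrichment_result"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  if (format == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("jsonlite is required for JSON output", call. = FALSE)
    jsonlite::write_json(as.data.frame(res), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.table(as.data.frame(res), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
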