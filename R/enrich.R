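#' Hypergeometric term enrichment against a whole-proteome background
#'
#' For every term with at least one background member, tests whether the
#' study set (the census) is enriched for the term's proteins. With `N` the
#' background size, `K` the term's background members, `n` the study size and
#' `k` the term's study members, the p-value is the upper hypergeometric tail
#' `P(X >= k)` (equivalently a one-sided Fisher test). Benjamini-Hochberg
#' adjusted values are attached via [bh_fdr()].
#'
#' @param study Character vector of study accessions; must be a subset of
#'   `background`.
#' @param background Character vector of background accessions (typically the
#'   whole proteome).
#' @param terms Data frame with columns `term`, `protein` (one membership per
#'   row), or a named list of accession vectors.
#' @param fdr_max Optional reporting cutoff on the adjusted value; `NULL`
#'   (default) reports all terms. The conventional stringent census cutoff is
#'   0.001.
#' @return Data frame sorted by `fdr` then `p_value` with columns `term`,
#'   `k`, `K`, `n`, `N`, `p_value`, `fdr`.
#' @examples
#' bg <- sprintf("P%02d", 1:10)
#' enrich_terms(bg[1:4], bg, list(t1 = bg[1:5]))
#' @export
enrich_terms <- function(study, background, terms, fdr_max = NULL) {
  study <- unique(study)
  background <- unique(background)
  if (length(background) == 0) usage_error("background must be nonempty")
  stray <- setdiff(study, background)
  if (length(stray) > 0)
    usage_error("study accessions missing from background: %s",
                paste(utils::head(stray, 10), collapse = ", "))
  if (is.data.frame(terms)) {
    require_columns(terms, c("term", "protein"), "term map")
    terms <- split(terms$protein, terms$term)
  }
  terms <- lapply(terms, function(v) unique(intersect(v, background)))
  terms <- terms[vapply(terms, length, integer(1)) >= 1L]
  N <- length(background)
  n <- length(study)
  K <- vapply(terms, length, integer(1))
  k <- vapply(terms, function(v) length(intersect(v, study)), integer(1))
  p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term = names(terms), k = k, K = K, n = n, N = N,
                    p_value = p, fdr = bh_fdr(p), stringsAsFactors = FALSE)
  out <- out[order(out$fdr, out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(fdr_max)) out <- out[out$fdr <= fdr_max, , drop = FALSE]
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH false-discovery-rate step-up: with `m` p-values sorted
#' ascending, the i-th adjusted value is `min_{j >= i} (m/j) p_(j)`, clipped
#' to \[0, 1\]. Output order matches input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as `p`.
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03))
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    usage_error("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
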