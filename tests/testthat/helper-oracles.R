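# Shared fixtures and independent oracle implementations used by the tests.

# a fully specified hit row with sensible defaults
mk_hit <- function(protein = "SYN00001", family = "FamA", ali_from = 1,
                   ali_to = 100, ie = 1e-6, model_length = 100, hmm_from = 1,
                   hmm_to = model_length, clan = "", full = ie / 10,
                   bit = 100) {
  data.frame(protein = protein, family = family, clan = clan,
             ali_from = ali_from, ali_to = ali_to, hmm_from = hmm_from,
             hmm_to = hmm_to, model_length = model_length,
             full_sequence_evalue = full, independent_evalue = ie,
             bit_score = bit, stringsAsFactors = FALSE)
}

# random filtered-hit instances for one protein (coordinates may overlap
# arbitrarily; occasional duplicated E-values exercise the tie-breaks)
random_hit_set <- function(n, protein = "SYN00001", L = 400) {
  from <- sample.int(L - 10L, n, replace = TRUE)
  len <- sample(10:120, n, replace = TRUE)
  to <- pmin(from + len - 1L, L)
  ie <- 10^stats::runif(n, -15, -3.1)
  dup <- which(stats::runif(n) < 0.2 & seq_len(n) > 1)
  if (length(dup) > 0)
    ie[dup] <- ie[sample.int(min(dup) - 1, length(dup), replace = TRUE)]
  ml <- to - from + 1L
  do.call(rbind, lapply(seq_len(n), function(i) {
    mk_hit(protein, sample(LETTERS[1:15], 1), from[i], to[i], ie[i],
           model_length = ml[i], hmm_to = ml[i])
  }))
}

# naive O(n^2) re-implementation of the greedy acceptance definition:
# candidates ranked by (independent E-value, longer alignment, start,
# family, input position); a candidate joins the accepted set iff its
# residue intersection with every accepted interval has length <= tol
naive_resolve <- function(hits, tol = 25) {
  n <- nrow(hits)
  len <- hits$ali_to - hits$ali_from + 1
  remaining <- seq_len(n)
  ranked <- integer(0)
  while (length(remaining) > 0) {
    best <- remaining[1]
    for (i in remaining[-1]) {
      if (hits$independent_evalue[i] < hits$independent_evalue[best] ||
          (hits$independent_evalue[i] == hits$independent_evalue[best] &&
           (len[i] > len[best] ||
            (len[i] == len[best] &&
             (hits$ali_from[i] < hits$ali_from[best] ||
              (hits$ali_from[i] == hits$ali_from[best] &&
               (hits$family[i] < hits$family[best] ||
                (hits$family[i] == hits$family[best] && i < best)))))))) {
        best <- i
      }
    }
    ranked <- c(ranked, best)
    remaining <- setdiff(remaining, best)
  }
  accepted <- integer(0)
  for (i in ranked) {
    ok <- TRUE
    for (j in accepted) {
      shared <- length(intersect(seq(hits$ali_from[i], hits$ali_to[i]),
                                 seq(hits$ali_from[j], hits$ali_to[j])))
      if (shared > tol) { ok <- FALSE; break }
    }
    if (ok) accepted <- c(accepted, i)
  }
  sort(accepted)
}

# exact hypergeometric upper tail by direct enumeration of the pmf
hyper_tail_oracle <- function(N, K, n, k) {
  i <- k:min(K, n)
  if (length(i) == 0 || k > min(K, n)) return(0)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# hand step-up BH: running minimum of m*p_(j)/j from the largest p down
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (r in m:1) {
    running <- min(running, m * p[o[r]] / r)
    adj[o[r]] <- min(1, running)
  }
  adj
}

# key identifying one hit row regardless of ordering
hit_key <- function(h) {
  paste(h$family, h$ali_from, h$ali_to, signif(h$independent_evalue, 12), sep = "|")
}

md5_tree <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = FALSE))
  sums <- tools::md5sum(file.path(dir, files))
  stats::setNames(unname(sums), files)
}

default_edge <- function(database, score, type = "physical",
                         method_score = NA_real_, a = "P60709", b = "SYN00001") {
  data.frame(database = database, a = a, b = b, score = score,
             method_score = method_score, interaction_type = type,
             stringsAsFactors = FALSE)
}
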