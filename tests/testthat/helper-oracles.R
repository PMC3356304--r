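# Independent oracles used to pin expected values. These deliberately avoid
# the package's own code paths: brute-force enumeration and closed forms
# only.

# Exact inclusion probabilities of weighted sampling without replacement
# (exponent-key scheme == successive sampling proportional to m): enumerate
# every ordered selection of N items and accumulate its probability.
ss_inclusion_probs <- function(m, N) {
  n <- length(m)
  incl <- numeric(n)
  recurse <- function(remaining, chosen, prob) {
    if (length(chosen) == N) {
      incl[chosen] <<- incl[chosen] + prob
      return(invisible())
    }
    for (i in remaining) {
      recurse(setdiff(remaining, i), c(chosen, i),
              prob * m[i] / sum(m[remaining]))
    }
  }
  recurse(seq_len(n), integer(), 1)
  incl
}

# Exact probability of each unordered N-subset under the same scheme.
ss_set_probs <- function(m, N) {
  n <- length(m)
  out <- new.env()
  recurse <- function(remaining, chosen, prob) {
    if (length(chosen) == N) {
      key <- paste(sort(chosen), collapse = ",")
      out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + prob
      return(invisible())
    }
    for (i in remaining) {
      recurse(setdiff(remaining, i), c(chosen, i),
              prob * m[i] / sum(m[remaining]))
    }
  }
  recurse(seq_len(n), integer(), 1)
  sets <- ls(out)
  setNames(vapply(sets, function(k) out[[k]], 0), sets)
}

# Upper-tail hypergeometric P by exhaustive subset enumeration: draw N of n
# genes uniformly, pathway = first K genes, count subsets with overlap >= k.
hyper_enum_p <- function(k, K, N, n) {
  subs <- utils::combn(n, N)
  hits <- colSums(matrix(subs %in% seq_len(K), nrow = N))
  mean(hits >= k)
}

# Two-sided Fisher exact P by fixed-margin enumeration: sum hypergeometric
# probabilities of all tables no more probable than the observed one
# (standard relative tolerance for floating-point ties).
fisher_enum_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) return(1)
  x <- max(0, c1 - r2):min(c1, r1)
  pr <- stats::dhyper(x, r1, r2, c1)
  pobs <- stats::dhyper(a, r1, r2, c1)
  sum(pr[pr <= pobs * (1 + 1e-7)])
}
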