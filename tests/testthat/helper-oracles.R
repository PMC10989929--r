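# Independent oracles used across the suite. These deliberately share no
# code with the implementation they check.

# Exhaustive per-bond scan: for every bond b (between residues b and
# b+1) with b+2 <= length and b-2 >= 1, test the +2U and -3/4A rules by
# direct substring inspection.
brute_scan <- function(seq) {
  s <- chartr("Tt", "UU", toupper(seq))
  n <- nchar(s)
  at <- function(i) substr(s, i, i)
  rows <- list()
  for (b in 3:(n - 2)) {
    p2 <- at(b + 2) == "U"
    m3 <- at(b - 2) == "A"
    m4 <- if (b - 3 >= 1) at(b - 3) == "A" else FALSE
    if (p2 || m3 || m4) {
      rows[[length(rows) + 1]] <- data.frame(
        bond = b, plus2_u = p2, minus34_a = m3 || m4,
        both = p2 && (m3 || m4)
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(bond = integer(), plus2_u = logical(),
                      minus34_a = logical(), both = logical()))
  }
  do.call(rbind, rows)
}

# Regex-style run enumeration of U tracts.
brute_u_tracts <- function(seq, min_len = 6) {
  s <- chartr("Tt", "UU", toupper(seq))
  m <- gregexpr(sprintf("U{%d,}", min_len), s)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(), end = integer()))
  }
  data.frame(start = as.integer(m),
             end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Profiled grid search over (lambda, n0) for the exponential-decay least
# squares problem. RSS(lambda, n0) = sum(rq^2) - 2 n0 a(lambda) +
# n0^2 b(lambda) with a = sum(rq * e), b = sum(e^2), evaluated on an
# n_grid x n_grid lattice centred on (lambda_c, n0_c).
grid_fit_oracle <- function(time, rq, lambda_c, n0_c, n_grid = 2000,
                            span = c(0.7, 1.3)) {
  lambda_grid <- seq(span[1] * lambda_c, span[2] * lambda_c,
                     length.out = n_grid)
  n0_grid <- seq(span[1] * n0_c, span[2] * n0_c, length.out = n_grid)
  E <- exp(-outer(lambda_grid, time))      # n_grid x n
  a <- as.vector(E %*% rq)
  b <- rowSums(E^2)
  rss <- sum(rq^2) - 2 * outer(a, n0_grid) + outer(b, n0_grid^2)
  idx <- arrayInd(which.min(rss), dim(rss))
  list(lambda = lambda_grid[idx[1]], n0 = n0_grid[idx[2]],
       rss = min(rss))
}

# A random RNA string over the full alphabet.
random_rna <- function(n, seed) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = ""
  ))
}

# A noiseless relative-quantity course from the closed-form decay model.
exact_course <- function(t_half, timepoints = c(0, 5, 10, 30), n0 = 1,
                         series = "s1") {
  tibble::tibble(
    time_min = timepoints,
    rq = n0 * exp(-log(2) / t_half * timepoints),
    series = series
  )
}

# Full pipeline estimate of the termination fraction for one simulated
# condition: exact intensity fold change from the generative model,
# decay constants re-estimated from simulated chase data.
recover_termination <- function(params, condition = "cond") {
  rq <- delta_delta_ct(simulate_chase(params, condition = condition))
  fits <- fit_decay(rq)
  lam <- function(comp) fits$lambda[fits$compartment == comp]
  ss <- steady_state_abundance(params)
  fc_int <- ss$intensity[ss$compartment == "UTR"] /
    ss$intensity[ss$compartment == "ORF"]
  termination_fraction(fc_int * lam("UTR") / lam("ORF"))
}
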