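# Independent brute-force oracles, coded naively (explicit loops, no shared
# helpers with the package) so they can certify the vectorized paths.

# average rank of |x| computed by counting, not by base rank()
oracle_abs_ranks <- function(x) {
  a <- abs(x)
  out <- numeric(length(a))
  for (i in seq_along(a)) {
    smaller <- sum(a < a[i])
    equal <- sum(a == a[i])
    # average of positions smaller+1 .. smaller+equal
    out[i] <- smaller + (equal + 1) / 2
  }
  out
}

# position-by-position running-sum enrichment score
oracle_es <- function(gene_set, ref_genes, ref_z, w_exp = 1) {
  ord <- order(-ref_z, ref_genes, method = "radix")
  genes <- ref_genes[ord]
  z <- ref_z[ord]
  n <- length(genes)
  m <- length(gene_set)
  denom <- 0
  for (g in gene_set) denom <- denom + abs(z[which(genes == g)])^w_exp
  running <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (genes[i] %in% gene_set) {
      running <- running + abs(z[i])^w_exp / denom
    } else {
      running <- running - 1 / (n - m)
    }
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# literal signed-rank connection strength evaluation
oracle_css <- function(up, down, up_z, down_z, ref_genes, ref_z) {
  r_ref <- oracle_abs_ranks(ref_z) * sign(ref_z)
  names(r_ref) <- ref_genes
  genes <- c(up, down)
  qz <- c(up_z, down_z)
  r_q <- oracle_abs_ranks(qz) * sign(qz)
  c_raw <- 0
  for (i in seq_along(genes)) c_raw <- c_raw + r_ref[[genes[i]]] * r_q[i]
  mags_ref <- sort(abs(r_ref), decreasing = TRUE)[seq_along(genes)]
  mags_q <- sort(abs(r_q), decreasing = TRUE)
  c_max <- sum(mags_ref * mags_q)
  c_raw / c_max
}

# literal extreme-sum evaluation
oracle_xsum <- function(up, down, ref_genes, ref_z, m) {
  ord <- order(-ref_z, ref_genes, method = "radix")
  kept <- c(ref_genes[ord][1:m], rev(ref_genes[ord])[1:m])
  zstar <- ifelse(ref_genes %in% kept, ref_z, 0)
  names(zstar) <- ref_genes
  total <- 0
  for (g in up) total <- total + zstar[[g]]
  for (g in down) total <- total - zstar[[g]]
  total
}

# random scoring instance: a reference signature plus a query extreme set
random_instance <- function(n, k, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n))
  ref <- signature_record("ref", genes, rnorm(n))
  qz <- rnorm(n)
  q <- signature_record("q", genes, qz)
  list(ref = ref, query = q, extremes = select_extreme_genes(q, k))
}

# small repository + aligned query for screen-level tests
small_screen_fixture <- function(n_genes = 120, n_sigs = 60, seed = 5,
                                 planted = list()) {
  q <- simulate_query(n_genes, seed = seed)
  spec <- simulation_spec(n_genes = n_genes, n_signatures = n_sigs,
                          planted = planted, seed = seed)
  sim <- simulate_repository(spec, query = q)
  list(query = q, repo = sim$repo, truth = sim$truth)
}
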