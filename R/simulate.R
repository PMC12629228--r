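#' Simulate a query signature
#'
#' Gene-level z-scores drawn i.i.d. standard normal over a generated gene
#' universe (`G00001`, `G00002`, ...) — the simplest model consistent with
#' moderated z-score (level-5 style) signature semantics.
#'
#' @param n_genes universe size (>= 4).
#' @param seed RNG seed.
#' @param sig_id identifier for the query (default `"query"`).
#' @return a [signature_record()].
#' @export
simulate_query <- function(n_genes = 1000L, seed = 1L, sig_id = "query") {
  n_genes <- as.integer(n_genes)
  .assert(n_genes >= 4L, "n_genes must be >= 4")
  genes <- sprintf("G%05d", seq_len(n_genes))
  z <- .with_seed(derive_seed(seed, "query", sig_id), rnorm(n_genes))
  signature_record(sig_id, genes, z)
}

#' Simulation specification for a synthetic reference repository
#'
#' @param n_genes shared gene-universe size (default 1000).
#' @param n_signatures repository size (default 500).
#' @param planted list of planted-signal descriptions, each a list with
#'   `kind` (`"mimic"` or `"reversal"`), `alpha` (signal weight > 0) and
#'   `noise_sd` (>= 0). E.g.
#'   `list(list(kind = "reversal", alpha = 1, noise_sd = 0.3))`.
#' @param seed master seed; the whole repository is reproducible from it.
#' @param compounds,cell_lines label pools for the metadata annotations.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 1000L, n_signatures = 500L,
                            planted = list(), seed = 1L,
                            compounds = sprintf("cpd_%03d", 1:50),
                            cell_lines = c("A375", "MCF7", "PC3", "HT29",
                                           "HA1E")) {
  n_genes <- as.integer(n_genes); n_signatures <- as.integer(n_signatures)
  .assert(n_genes >= 4L, "n_genes must be >= 4")
  .assert(n_signatures >= 1L, "n_signatures must be >= 1")
  for (p in planted) {
    .assert(is.list(p) && p$kind %in% c("mimic", "reversal"),
            "each planted entry needs kind 'mimic' or 'reversal'")
    .assert(is.numeric(p$alpha) && p$alpha > 0, "planted alpha must be > 0")
    .assert(is.numeric(p$noise_sd) && p$noise_sd >= 0,
            "planted noise_sd must be >= 0")
  }
  .assert(length(planted) < n_signatures,
          "planted count must be smaller than n_signatures")
  structure(list(n_genes = n_genes, n_signatures = n_signatures,
                 planted = planted, seed = as.integer(seed),
                 compounds = compounds, cell_lines = cell_lines),
            class = "simulation_spec")
}

#' Simulate a reference repository with known ground truth
#'
#' Null signatures have i.i.d. standard-normal z over the shared universe.
#' A planted mimic of query q is `alpha * standardized(q) + eps` and a
#' planted reversal `-alpha * standardized(q) + eps`, with eps i.i.d.
#' normal(0, noise_sd); `standardized(q)` is q centered and scaled to unit
#' variance so that alpha is comparable across queries. Planted signatures
#' occupy the last slots of the repository and are flagged in the returned
#' truth table.
#'
#' @param spec a [simulation_spec()].
#' @param query the query [signature_record()] planted signals derive from;
#'   if `NULL` and planting is requested, a query is generated from the spec
#'   seed (and returned).
#' @return list with `repo` (a `sig_repository`), `truth` (data.frame:
#'   sig_id, kind, alpha, noise_sd) and `query`.
#' @export
simulate_repository <- function(spec, query = NULL) {
  .assert(inherits(spec, "simulation_spec"), "spec must be a simulation_spec")
  n_planted <- length(spec$planted)
  if (n_planted > 0L && is.null(query))
    query <- simulate_query(spec$n_genes, seed = spec$seed)
  if (!is.null(query))
    .assert(length(query$gene_ids) == spec$n_genes,
            "query universe size differs from spec n_genes")
  genes <- if (is.null(query)) sprintf("G%05d", seq_len(spec$n_genes))
           else query$gene_ids
  n_null <- spec$n_signatures - n_planted
  ids <- sprintf("SIG_%05d", seq_len(spec$n_signatures))
  zmat <- matrix(NA_real_, nrow = spec$n_genes, ncol = spec$n_signatures,
                 dimnames = list(genes, ids))
  .with_seed(derive_seed(spec$seed, "repository", "null"), {
    if (n_null > 0L)
      zmat[, seq_len(n_null)] <- rnorm(spec$n_genes * n_null)
  })
  truth <- data.frame(sig_id = character(0), kind = character(0),
                      alpha = numeric(0), noise_sd = numeric(0),
                      stringsAsFactors = FALSE)
  if (n_planted > 0L) {
    qs <- (query$z - mean(query$z)) / sd(query$z)
    for (i in seq_len(n_planted)) {
      p <- spec$planted[[i]]
      sgn <- if (p$kind == "mimic") 1 else -1
      eps <- .with_seed(derive_seed(spec$seed, "repository", "planted", i),
                        rnorm(spec$n_genes, sd = p$noise_sd))
      zmat[, n_null + i] <- sgn * p$alpha * qs + eps
      truth <- rbind(truth, data.frame(
        sig_id = ids[n_null + i], kind = p$kind, alpha = p$alpha,
        noise_sd = p$noise_sd, stringsAsFactors = FALSE))
    }
  }
  meta <- .with_seed(derive_seed(spec$seed, "repository", "metadata"),
    data.frame(
      sig_id = ids,
      compound = sample(spec$compounds, spec$n_signatures, replace = TRUE),
      cell_line = sample(spec$cell_lines, spec$n_signatures, replace = TRUE),
      dose = sample(c("10 uM", "1 uM", "0.1 uM"), spec$n_signatures,
                    replace = TRUE),
      time = sample(c("6 h", "24 h"), spec$n_signatures, replace = TRUE),
      pert_type = "trt_cp",
      stringsAsFactors = FALSE))
  if (n_planted > 0L)
    meta$compound[seq.int(n_null + 1L, spec$n_signatures)] <-
      sprintf("planted_%s_%02d", vapply(spec$planted, `[[`, character(1),
                                        "kind"), seq_len(n_planted))
  list(repo = repository_from_matrix(zmat, meta,
                                     backend_descriptor = "memory:simulated"),
       truth = truth, query = query)
}
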