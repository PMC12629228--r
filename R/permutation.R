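#' Build a permutation null background for CSS or XSum
#'
#' Each iteration draws a random extreme-gene set — 2K distinct genes sampled
#' uniformly without replacement from the reference universe, randomly split
#' into an up list and a down list of K each, with a random importance order
#' (the query rank magnitudes 1..2K are a uniform random permutation) — and
#' records the method's statistic against the fixed reference. This is the
#' query-independent reading of pre-permuting each reference signature, and
#' it lets backgrounds be precomputed once per reference.
#'
#' Draws are generated in antithetic pairs: every sampled extreme set is
#' followed by its up/down-swapped mirror, whose statistic is exactly the
#' negated value. The mirror is equally likely under the null, so the
#' marginal distribution is unchanged, while the stored sample becomes
#' sign-symmetric — making lower- and upper-tail p-values exactly dual
#' (`p_lower(-x) = p_upper(x)`), so that negating a query and flipping the
#' screen direction reproduces a screen exactly.
#'
#' The RNG substream seed is derived deterministically from
#' `(seed, sig_id, method, K)`, so backgrounds are bit-identical regardless of
#' the order (or parallelism) in which they are built.
#'
#' @param ref reference [signature_record()].
#' @param method `"css"` or `"xsum"`.
#' @param K extreme-gene count per side; `2K <= N` required.
#' @param n_perm number of iterations (default 10000).
#' @param seed master seed.
#' @param ref_extreme_n reference-side truncation for XSum (default K).
#' @return an object of class `perm_background` with fields `sig_id`,
#'   `method`, `K`, `ref_extreme_n`, `n_perm`, `seed` (the derived substream
#'   seed), and `null_values` (length `n_perm`).
#' @export
build_background <- function(ref, method = c("css", "xsum"), K = 50L,
                             n_perm = 10000L, seed = 1L,
                             ref_extreme_n = K) {
  method <- match.arg(method)
  .assert(is_signature(ref), "ref must be a signature_record")
  K <- as.integer(K); n_perm <- as.integer(n_perm)
  n <- length(ref$gene_ids)
  .assert(2L * K <= n, sprintf("2K = %d exceeds universe size %d", 2L * K, n))
  .assert(n_perm >= 1L, "n_perm must be >= 1")
  sub_seed <- derive_seed(seed, ref$sig_id, method, K)
  k2 <- 2L * K
  n_draw <- (n_perm + 1L) %/% 2L   # each draw also yields its mirror
  draws <- numeric(n_draw)
  if (method == "xsum") {
    zs <- xsum_truncated_z(ref$z, ref$gene_ids, as.integer(ref_extreme_n))
    .with_seed(sub_seed, {
      for (i in seq_len(n_draw)) {
        idx <- sample.int(n, k2)
        draws[i] <- sum(zs[idx[seq_len(K)]]) -
          sum(zs[idx[seq.int(K + 1L, k2)]])
      }
    })
  } else {
    r_ref <- css_reference_ranks(ref$z)
    c_max <- css_cmax(r_ref, seq.int(k2, 1L))
    signs <- rep(c(1, -1), each = K)
    .with_seed(sub_seed, {
      for (i in seq_len(n_draw)) {
        idx <- sample.int(n, k2)
        mags <- sample.int(k2)
        draws[i] <- sum(r_ref[idx] * mags * signs) / c_max
      }
    })
  }
  null_values <- as.vector(rbind(draws, -draws))[seq_len(n_perm)]
  structure(
    list(sig_id = ref$sig_id, method = method, K = K,
         ref_extreme_n = if (method == "xsum") as.integer(ref_extreme_n)
                         else NA_integer_,
         n_perm = n_perm, seed = sub_seed, null_values = null_values),
    class = "perm_background"
  )
}

#' @export
print.perm_background <- function(x, ...) {
  cat("<permutation background> ", x$sig_id, " / ", x$method, " / K=", x$K,
      ": ", x$n_perm, " null values (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Empirical p-value from a permutation background
#'
#' One-sided add-one rule: for the upper tail,
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`; lower tail analogously
#' with `<=`. The add-one convention bounds p away from zero
#' (`p >= 1/(n_perm+1)`) and permits `p = 1`.
#'
#' @param observed observed statistic.
#' @param background a [build_background()] result.
#' @param tail `"upper"` (mimicry screens) or `"lower"` (reversal screens).
#' @return p-value in `(0, 1]`.
#' @export
empirical_pvalue <- function(observed, background,
                             tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  .assert(inherits(background, "perm_background"),
          "background must be a perm_background")
  nv <- background$null_values
  .assert(length(nv) >= 1L, "empty background")
  .assert(is.finite(observed), "observed statistic must be finite")
  hits <- if (tail == "upper") sum(nv >= observed) else sum(nv <= observed)
  (1 + hits) / (length(nv) + 1)
}

#' Persist and reload permutation backgrounds
#'
#' One self-describing file per reference signature (all of its
#' `(method, K)` arrays together) plus a tab-delimited manifest listing
#' coverage. Write-then-read reproduces every field exactly.
#'
#' @param backgrounds list of `perm_background` objects.
#' @param dir store directory (created if needed).
#' @return `background_store_write`: the directory, invisibly.
#' @export
background_store_write <- function(backgrounds, dir) {
  .assert(is.list(backgrounds) && length(backgrounds) >= 1L,
          "need at least one background")
  .assert(all(vapply(backgrounds, inherits, logical(1), "perm_background")),
          "all elements must be perm_background objects")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- vapply(backgrounds, `[[`, character(1), "sig_id")
  files <- sprintf("bg_%05d.rds", match(ids, unique(ids)))
  manifest <- data.frame(
    sig_id = ids,
    method = vapply(backgrounds, `[[`, character(1), "method"),
    K = vapply(backgrounds, `[[`, integer(1), "K"),
    n_perm = vapply(backgrounds, `[[`, integer(1), "n_perm"),
    seed = vapply(backgrounds, `[[`, integer(1), "seed"),
    file = files,
    stringsAsFactors = FALSE
  )
  .assert(!anyDuplicated(manifest[, c("sig_id", "method", "K")]),
          "duplicate (sig_id, method, K) among backgrounds")
  for (f in unique(files)) {
    bundle <- backgrounds[files == f]
    names(bundle) <- paste(
      vapply(bundle, `[[`, character(1), "method"),
      vapply(bundle, `[[`, integer(1), "K"), sep = ".")
    saveRDS(bundle, file.path(dir, f))
  }
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname background_store_write
#' @param sig_id,method,K key of the background to fetch.
#' @param n_perm if non-NULL, the stored background must have exactly this
#'   permutation count (guards against stale stores).
#' @return `background_store_read`: the requested `perm_background`.
#' @export
background_store_read <- function(dir, sig_id, method, K, n_perm = NULL) {
  manifest <- background_store_manifest(dir)
  row <- manifest[manifest$sig_id == sig_id & manifest$method == method &
                    manifest$K == as.integer(K), , drop = FALSE]
  .assert(nrow(row) == 1L,
          sprintf("no stored background for (sig_id=%s, method=%s, K=%d)",
                  sig_id, method, as.integer(K)))
  bundle <- readRDS(file.path(dir, row$file))
  bg <- bundle[[paste(method, as.integer(K), sep = ".")]]
  .assert(!is.null(bg), "store file inconsistent with manifest for ", sig_id)
  if (!is.null(n_perm))
    .assert(bg$n_perm == as.integer(n_perm),
            sprintf(paste0("stored background for (%s, %s, K=%d) has n_perm=%d, ",
                           "but n_perm=%d requested: stale background store"),
                    sig_id, method, as.integer(K), bg$n_perm,
                    as.integer(n_perm)))
  bg
}

#' @rdname background_store_write
#' @export
background_store_manifest <- function(dir) {
  path <- file.path(dir, "manifest.tsv")
  .assert(file.exists(path), "no background manifest at ", path)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c("character", "character", "integer",
                                   "integer", "integer", "character"))
}

#' Build the full background store for a repository
#'
#' One CSS and one XSum background per reference signature for each requested
#' K. Work is partitioned over references with [parallel::mclapply()];
#' per-reference derived seeds make the result independent of scheduling.
#'
#' @param repo a `sig_repository`.
#' @param K_values integer vector of extreme counts to cover
#'   (default `c(50, 100, 150, 200)`, the selectable values).
#' @param n_perm iterations per background.
#' @param seed master seed.
#' @param dir if non-NULL, write the store there and return the directory;
#'   otherwise return the list of backgrounds.
#' @param threads worker processes.
#' @export
build_background_store <- function(repo, K_values = c(50L, 100L, 150L, 200L),
                                   n_perm = 10000L, seed = 1L, dir = NULL,
                                   threads = 1L) {
  .assert(is_repository(repo), "repo must be a sig_repository")
  K_values <- as.integer(K_values)
  .assert(all(2L * K_values <= length(repo$gene_universe)),
          "some K in K_values exceeds half the universe size")
  ids <- repo_sig_ids(repo)
  worker <- function(id) {
    ref <- repo_signature(repo, id)
    out <- list()
    for (K in K_values) for (m in c("css", "xsum"))
      out[[paste(m, K, sep = ".")]] <-
        build_background(ref, m, K = K, n_perm = n_perm, seed = seed,
                         ref_extreme_n = K)
    out
  }
  res <- if (threads > 1L)
    parallel::mclapply(ids, worker, mc.cores = threads)
  else lapply(ids, worker)
  backgrounds <- unlist(res, recursive = FALSE, use.names = FALSE)
  if (is.null(dir)) backgrounds else background_store_write(backgrounds, dir)
}
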