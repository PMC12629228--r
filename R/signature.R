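#' Construct a perturbation signature
#'
#' A signature is one perturbation's genome-wide differential-expression
#' pattern, encoded as gene-level z-scores (perturbation vs control), plus
#' free-text metadata (compound, cell line, dose, exposure time, ...).
#'
#' @param sig_id unique identifier (non-empty string).
#' @param gene_ids character vector of gene identifiers, no duplicates.
#'   Identifiers are opaque, case-sensitive strings; no symbol/ID conversion
#'   is attempted.
#' @param z numeric vector of signed z-scores, parallel to `gene_ids`,
#'   all finite.
#' @param metadata named list of character scalars (e.g. `compound`,
#'   `cell_line`, `dose`, `time`, `pert_type`); all optional.
#' @return an object of class `sig_signature`.
#' @examples
#' s <- signature_record("sig1", c("TP53", "MYC"), c(1.2, -0.4))
#' @export
signature_record <- function(sig_id, gene_ids, z, metadata = list()) {
  .assert(is.character(sig_id) && length(sig_id) == 1L && nzchar(sig_id),
          "sig_id must be a non-empty string")
  gene_ids <- as.character(gene_ids)
  z <- as.numeric(z)
  .assert(length(gene_ids) == length(z),
          "signature '", sig_id, "': gene_ids and z lengths differ (",
          length(gene_ids), " vs ", length(z), ")")
  .assert(length(gene_ids) >= 2L, "signature '", sig_id, "': needs >= 2 genes")
  .assert(!anyDuplicated(gene_ids),
          "signature '", sig_id, "': duplicate gene identifiers")
  .assert(all(is.finite(z)),
          "signature '", sig_id, "': non-finite z values")
  .assert(is.list(metadata), "metadata must be a list")
  structure(
    list(sig_id = sig_id, gene_ids = gene_ids, z = z,
         metadata = lapply(metadata, as.character)),
    class = "sig_signature"
  )
}

#' @export
print.sig_signature <- function(x, ...) {
  cat("<signature> ", x$sig_id, ": ", length(x$gene_ids), " genes, z in [",
      sprintf("%.3g", min(x$z)), ", ", sprintf("%.3g", max(x$z)), "]\n", sep = "")
  if (length(x$metadata))
    cat("  metadata: ",
        paste(names(x$metadata), unlist(x$metadata), sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

is_signature <- function(x) inherits(x, "sig_signature")

#' Construct a signature repository
#'
#' A repository is a set of reference signatures sharing one gene universe.
#' Members are aligned to the intersection of their gene sets, so every
#' member reports a z value for every universe gene (missing genes are
#' disallowed post-alignment; genes outside the intersection are dropped).
#'
#' @param signatures list of [signature_record()] objects with unique ids.
#' @param backend_descriptor free-text storage description
#'   (`"memory"`, `"gct-file:<path>"`, `"json-directory:<path>"`, ...).
#' @return an object of class `sig_repository` with fields `gene_universe`
#'   (ordered character vector), `zmat` (genes x signatures numeric matrix),
#'   `meta` (data.frame of metadata, one row per signature) and
#'   `backend_descriptor`.
#' @export
signature_repository <- function(signatures, backend_descriptor = "memory") {
  .assert(is.list(signatures) && length(signatures) >= 1L,
          "repository needs at least one signature")
  .assert(all(vapply(signatures, is_signature, logical(1))),
          "all elements must be signature_record objects")
  ids <- vapply(signatures, `[[`, character(1), "sig_id")
  .assert(!anyDuplicated(ids), "duplicate sig_ids in repository: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  universe <- signatures[[1L]]$gene_ids
  for (s in signatures[-1L]) universe <- intersect(universe, s$gene_ids)
  .assert(length(universe) >= 2L,
          "gene universe (intersection over member signatures) has < 2 genes")
  zmat <- vapply(signatures, function(s) {
    s$z[match(universe, s$gene_ids)]
  }, numeric(length(universe)))
  zmat <- matrix(zmat, nrow = length(universe),
                 dimnames = list(universe, ids))
  meta_fields <- unique(unlist(lapply(signatures, function(s) names(s$metadata))))
  meta <- data.frame(sig_id = ids, stringsAsFactors = FALSE)
  for (f in meta_fields) {
    meta[[f]] <- vapply(signatures, function(s) {
      v <- s$metadata[[f]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  }
  structure(
    list(gene_universe = universe, zmat = zmat, meta = meta,
         backend_descriptor = backend_descriptor),
    class = "sig_repository"
  )
}

#' Build a repository directly from a z-score matrix
#'
#' @param zmat numeric matrix, genes in rows (rownames = gene ids),
#'   signatures in columns (colnames = sig ids).
#' @param meta optional data.frame of per-signature metadata with a `sig_id`
#'   column matching `colnames(zmat)`.
#' @inheritParams signature_repository
#' @return a `sig_repository`.
#' @export
repository_from_matrix <- function(zmat, meta = NULL,
                                   backend_descriptor = "memory") {
  .assert(is.matrix(zmat) && is.numeric(zmat), "zmat must be a numeric matrix")
  .assert(!is.null(rownames(zmat)) && !is.null(colnames(zmat)),
          "zmat needs gene rownames and signature colnames")
  .assert(!anyDuplicated(rownames(zmat)), "duplicate gene ids in zmat rows")
  .assert(!anyDuplicated(colnames(zmat)), "duplicate sig ids in zmat columns")
  .assert(all(is.finite(zmat)), "zmat contains non-finite values")
  if (is.null(meta)) {
    meta <- data.frame(sig_id = colnames(zmat), stringsAsFactors = FALSE)
  } else {
    .assert("sig_id" %in% names(meta), "meta needs a sig_id column")
    .assert(setequal(meta$sig_id, colnames(zmat)),
            "meta sig_ids do not match zmat columns")
    meta <- meta[match(colnames(zmat), meta$sig_id), , drop = FALSE]
    rownames(meta) <- NULL
  }
  structure(
    list(gene_universe = rownames(zmat), zmat = zmat, meta = meta,
         backend_descriptor = backend_descriptor),
    class = "sig_repository"
  )
}

#' Build a repository from fetcher functions (remote-backend contract)
#'
#' Realizes the pluggable read contract a remote (e.g. REST) backend must
#' honor: list signature ids, report the gene universe, and fetch one
#' signature by id. Signatures are fetched eagerly; no operation behaves
#' differently by backend.
#'
#' @param list_ids function() -> character vector of sig_ids.
#' @param universe function() -> character vector of universe gene ids.
#' @param fetch function(sig_id) -> [signature_record()].
#' @param backend_descriptor free-text description of the endpoint.
#' @return a `sig_repository`.
#' @export
repository_from_fetcher <- function(list_ids, universe, fetch,
                                    backend_descriptor = "fetcher") {
  ids <- list_ids()
  .assert(length(ids) >= 1L, "backend lists no signatures")
  uni <- as.character(universe())
  sigs <- lapply(ids, fetch)
  repo <- signature_repository(sigs, backend_descriptor = backend_descriptor)
  .assert(setequal(repo$gene_universe, uni),
          "backend universe disagrees with fetched signatures")
  # preserve the backend's declared gene order
  repo$zmat <- repo$zmat[match(uni, repo$gene_universe), , drop = FALSE]
  repo$gene_universe <- uni
  repo
}

#' @export
print.sig_repository <- function(x, ...) {
  cat("<signature repository> ", ncol(x$zmat), " signatures x ",
      length(x$gene_universe), " genes [", x$backend_descriptor, "]\n", sep = "")
  invisible(x)
}

is_repository <- function(x) inherits(x, "sig_repository")

#' Number of signatures and universe accessors
#' @param repo a `sig_repository`.
#' @return `repo_sig_ids`: character vector of ids; `repo_signature`: one
#'   [signature_record()] aligned to the universe.
#' @export
repo_sig_ids <- function(repo) colnames(repo$zmat)

#' @rdname repo_sig_ids
#' @param sig_id id of the member signature to extract.
#' @export
repo_signature <- function(repo, sig_id) {
  .assert(sig_id %in% colnames(repo$zmat), "unknown sig_id: ", sig_id)
  md <- as.list(repo$meta[repo$meta$sig_id == sig_id, , drop = FALSE])
  md$sig_id <- NULL
  md <- md[!vapply(md, function(v) is.na(v[1]), logical(1))]
  signature_record(sig_id, repo$gene_universe, repo$zmat[, sig_id],
                   metadata = md)
}

#' Screen configuration
#'
#' @param K extreme-gene count per side (default 50, the conventional choice;
#'   100/150/200 are typical alternatives but any `K >= 1` with
#'   `2K <= universe` is accepted).
#' @param n_perm permutation count for CSS/XSum null backgrounds
#'   (default 10000).
#' @param vote_quantile fraction of a screen defining one method's vote
#'   (default 0.05, the top-5% rule).
#' @param direction `"positive"` (mimic screen) or `"negative"`
#'   (reversal screen).
#' @param seed master RNG seed; all randomness is derived from it.
#' @param ref_extreme_n reference-side extreme count for XSum (default = K).
#' @param min_overlap_frac minimum fraction of query genes that must be
#'   present in the repository universe (default 0.8); failure signals
#'   incompatible identifier namespaces.
#' @param sig_rule how a reference becomes "significant" for the WTCS gate:
#'   `"quantile"` (default; the same top-5% vote rule as the meta-score) or
#'   `"pvalue"` (empirical one-sided p <= 0.05 for CSS/XSum, two-sided
#'   t-approximation p <= 0.05 for Pearson/Spearman, quantile rule for
#'   cosine which has no p-value).
#' @param threads worker count for per-reference work; results are
#'   scheduling-independent.
#' @return an object of class `screen_config`.
#' @export
screen_config <- function(K = 50L, n_perm = 10000L, vote_quantile = 0.05,
                          direction = c("negative", "positive"), seed = 1L,
                          ref_extreme_n = K, min_overlap_frac = 0.8,
                          sig_rule = c("quantile", "pvalue"), threads = 1L) {
  direction <- match.arg(direction)
  sig_rule <- match.arg(sig_rule)
  K <- as.integer(K); n_perm <- as.integer(n_perm)
  ref_extreme_n <- as.integer(ref_extreme_n)
  .assert(K >= 1L, "K must be >= 1")
  .assert(n_perm >= 1L, "n_perm must be >= 1")
  .assert(vote_quantile > 0 && vote_quantile < 1,
          "vote_quantile must lie in (0, 1)")
  .assert(min_overlap_frac > 0 && min_overlap_frac <= 1,
          "min_overlap_frac must lie in (0, 1]")
  structure(
    list(K = K, n_perm = n_perm, vote_quantile = vote_quantile,
         direction = direction, seed = as.integer(seed),
         ref_extreme_n = ref_extreme_n, min_overlap_frac = min_overlap_frac,
         sig_rule = sig_rule, threads = as.integer(threads)),
    class = "screen_config"
  )
}

#' Align a query signature to a repository's gene universe
#'
#' Drops query genes absent from the universe (never imputes), preserving
#' the query's original relative gene order and z values. The retained
#' fraction is recorded in the result's metadata for logging.
#'
#' @param query a [signature_record()].
#' @param repo a repository built by [signature_repository()] or friends.
#' @param min_overlap_frac minimum retained fraction of query genes;
#'   below it an error signals incompatible identifier namespaces.
#' @return the restricted query signature (attribute `retained_frac` set).
#' @export
align_query <- function(query, repo, min_overlap_frac = 0.8) {
  .assert(is_signature(query), "query must be a signature_record")
  .assert(is_repository(repo), "repo must be a sig_repository")
  keep <- query$gene_ids %in% repo$gene_universe
  frac <- mean(keep)
  .assert(sum(keep) > 0L, "query and repository universes share no genes")
  .assert(frac >= min_overlap_frac,
          sprintf(paste0("only %.1f%% of query genes found in the repository ",
                         "universe (minimum %.1f%%): incompatible gene ",
                         "identifier namespaces?"),
                  100 * frac, 100 * min_overlap_frac))
  out <- signature_record(query$sig_id, query$gene_ids[keep], query$z[keep],
                          metadata = query$metadata)
  attr(out, "retained_frac") <- frac
  out
}

#' Select the extreme genes of a query signature
#'
#' The `up` list is the K genes with largest z (position 1 = most
#' up-regulated), the `down` list the K genes with smallest z (position 1 =
#' most down-regulated). Ties in z are broken by lexicographic gene id
#' (C-locale radix sort), making the selection reproducible across platforms
#' and invariant to storage order.
#'
#' @param query a signature, already aligned to the scoring universe.
#' @param K genes per side; requires `2K <=` gene count.
#' @return an object of class `extreme_gene_set` with fields `up`, `down`,
#'   `up_z`, `down_z`, `K`.
#' @export
select_extreme_genes <- function(query, K) {
  .assert(is_signature(query), "query must be a signature_record")
  K <- as.integer(K)
  n <- length(query$gene_ids)
  .assert(K >= 1L, "K must be >= 1")
  .assert(2L * K <= n,
          sprintf("2K = %d exceeds the %d scoreable query genes: choose a smaller K",
                  2L * K, n))
  ord_up <- order(-query$z, query$gene_ids, method = "radix")[seq_len(K)]
  ord_dn <- order(query$z, query$gene_ids, method = "radix")[seq_len(K)]
  structure(
    list(up = query$gene_ids[ord_up], down = query$gene_ids[ord_dn],
         up_z = query$z[ord_up], down_z = query$z[ord_dn], K = K),
    class = "extreme_gene_set"
  )
}

is_extreme_set <- function(x) inherits(x, "extreme_gene_set")

#' @export
print.extreme_gene_set <- function(x, ...) {
  cat("<extreme gene set> K =", x$K, "\n")
  cat("  up:  ", paste(head(x$up, 5), collapse = ", "),
      if (x$K > 5) ", ..." else "", "\n", sep = "")
  cat("  down:", paste(head(x$down, 5), collapse = ", "),
      if (x$K > 5) ", ..." else "", "\n", sep = "")
  invisible(x)
}
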