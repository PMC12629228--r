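#' Read a GCT matrix file into a signature repository
#'
#' Supports the GCT 1.2 and 1.3 text dialects (version line, dimension line,
#' header row; 1.3 additionally carries row- and column-metadata blocks).
#' Genes are rows, signatures are columns; 1.3 column metadata rows are
#' mapped into per-signature metadata.
#'
#' @param path path to a `.gct` file.
#' @return a `sig_repository`.
#' @export
read_gct <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  lines <- readLines(path)
  .assert(length(lines) >= 3L, "GCT file too short: ", path)
  version <- trimws(lines[1L])
  .assert(version %in% c("#1.2", "#1.3"),
          "line 1: unsupported GCT version line '", version, "'")
  dims <- suppressWarnings(as.integer(strsplit(trimws(lines[2L]), "\t")[[1L]]))
  if (version == "#1.2") {
    .assert(length(dims) == 2L && !anyNA(dims),
            "line 2: GCT 1.2 dimension line must be '<nrow>\\t<ncol>'")
    nrmeta <- 0L; ncmeta <- 0L
  } else {
    .assert(length(dims) == 4L && !anyNA(dims),
            "line 2: GCT 1.3 dimension line must have four integers")
    nrmeta <- dims[3L]; ncmeta <- dims[4L]
  }
  nr <- dims[1L]; nc <- dims[2L]
  header <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
  id_cols <- if (version == "#1.2") 2L else 1L + nrmeta
  .assert(length(header) == id_cols + nc,
          sprintf("line 3: header has %d fields, expected %d (%d id/meta + %d signatures)",
                  length(header), id_cols + nc, id_cols, nc))
  sig_ids <- header[(id_cols + 1L):length(header)]
  body_start <- 4L
  col_meta <- list()
  if (ncmeta > 0L) {
    for (i in seq_len(ncmeta)) {
      ln <- body_start + i - 1L
      fields <- strsplit(lines[ln], "\t", fixed = TRUE)[[1L]]
      .assert(length(fields) == id_cols + nc,
              "line ", ln, ": column-metadata row has wrong field count")
      col_meta[[fields[1L]]] <- fields[(id_cols + 1L):length(fields)]
    }
    body_start <- body_start + ncmeta
  }
  data_lines <- lines[seq.int(body_start, length(lines))]
  data_lines <- data_lines[nzchar(data_lines)]
  .assert(length(data_lines) == nr,
          sprintf("dimension line says %d genes but body has %d data rows",
                  nr, length(data_lines)))
  genes <- character(nr)
  zmat <- matrix(NA_real_, nrow = nr, ncol = nc)
  for (i in seq_len(nr)) {
    fields <- strsplit(data_lines[i], "\t", fixed = TRUE)[[1L]]
    ln <- body_start + i - 1L
    .assert(length(fields) == id_cols + nc,
            "line ", ln, ": data row has ", length(fields),
            " fields, expected ", id_cols + nc)
    genes[i] <- fields[1L]
    vals <- suppressWarnings(as.numeric(fields[(id_cols + 1L):length(fields)]))
    .assert(!anyNA(vals), "line ", ln, ": non-numeric z value in row '",
            fields[1L], "'")
    zmat[i, ] <- vals
  }
  .assert(!anyDuplicated(genes), "duplicate gene ids in GCT body")
  .assert(!anyDuplicated(sig_ids), "duplicate signature ids in GCT header")
  dimnames(zmat) <- list(genes, sig_ids)
  meta <- data.frame(sig_id = sig_ids, stringsAsFactors = FALSE)
  for (f in names(col_meta)) meta[[f]] <- col_meta[[f]]
  repository_from_matrix(zmat, meta,
                         backend_descriptor = paste0("gct-file:", path))
}

#' Write a signature repository as a GCT file
#'
#' Writes GCT 1.3 when per-signature metadata is present, otherwise 1.2.
#' `read_gct(write_gct(repo))` reproduces the repository exactly.
#'
#' @param repo a `sig_repository`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gct <- function(repo, path) {
  .assert(is_repository(repo), "repo must be a sig_repository")
  meta_fields <- setdiff(names(repo$meta), "sig_id")
  meta_fields <- meta_fields[vapply(meta_fields, function(f)
    !all(is.na(repo$meta[[f]])), logical(1))]
  nr <- nrow(repo$zmat); nc <- ncol(repo$zmat)
  con <- file(path, open = "wt")
  on.exit(close(con))
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  if (length(meta_fields) == 0L) {
    writeLines(c("#1.2", paste(nr, nc, sep = "\t"),
                 paste(c("NAME", "Description", colnames(repo$zmat)),
                       collapse = "\t")), con)
    for (i in seq_len(nr))
      writeLines(paste(c(rownames(repo$zmat)[i], "na",
                         fmt(repo$zmat[i, ])), collapse = "\t"), con)
  } else {
    writeLines(c("#1.3",
                 paste(nr, nc, 0L, length(meta_fields), sep = "\t"),
                 paste(c("id", colnames(repo$zmat)), collapse = "\t")), con)
    for (f in meta_fields) {
      vals <- repo$meta[[f]]
      vals[is.na(vals)] <- "NA"
      writeLines(paste(c(f, vals), collapse = "\t"), con)
    }
    for (i in seq_len(nr))
      writeLines(paste(c(rownames(repo$zmat)[i], fmt(repo$zmat[i, ])),
                       collapse = "\t"), con)
  }
  invisible(path)
}

#' Read signatures from the JSON dialect
#'
#' Each record is a JSON object with keys `sig_id`, `gene_ids`, `z`
#' (parallel arrays) and an optional `metadata` object (free-text values:
#' `pert_iname`/`compound`, `cell_line`, `dose`, `time`, `pert_type`,
#' `smiles`). `read_signature_json` reads one file; `read_signature_dir`
#' aggregates a directory of `*.json` records into a repository.
#'
#' @param path a JSON file (single record).
#' @return a [signature_record()].
#' @export
read_signature_json <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  rec <- tryCatch(jsonlite::fromJSON(path, simplifyVector = TRUE),
                  error = function(e)
                    stop("malformed JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  for (k in c("sig_id", "gene_ids", "z"))
    .assert(!is.null(rec[[k]]), path, ": missing required key '", k, "'")
  .assert(length(rec$gene_ids) == length(rec$z),
          path, ": gene_ids and z arrays have unequal length")
  md <- if (is.null(rec$metadata)) list() else as.list(rec$metadata)
  tryCatch(
    signature_record(as.character(rec$sig_id), rec$gene_ids,
                     as.numeric(rec$z), metadata = md),
    error = function(e) stop(path, ": ", conditionMessage(e), call. = FALSE))
}

#' @rdname read_signature_json
#' @param dir directory containing one JSON record per signature.
#' @return `read_signature_dir`: a `sig_repository`.
#' @export
read_signature_dir <- function(dir) {
  .assert(dir.exists(dir), "no such directory: ", dir)
  files <- sort(list.files(dir, pattern = "\\.json$", full.names = TRUE))
  .assert(length(files) >= 1L, "no .json records in ", dir)
  sigs <- lapply(files, read_signature_json)
  signature_repository(sigs,
                       backend_descriptor = paste0("json-directory:", dir))
}

#' @rdname read_signature_json
#' @param sig a [signature_record()] to serialize.
#' @param file output path for one record.
#' @export
write_signature_json <- function(sig, file) {
  .assert(is_signature(sig), "sig must be a signature_record")
  jsonlite::write_json(
    list(sig_id = sig$sig_id, gene_ids = sig$gene_ids, z = sig$z,
         metadata = sig$metadata),
    file, auto_unbox = TRUE, digits = I(17))
  invisible(file)
}

#' @rdname read_signature_json
#' @param repo repository to write as a directory of JSON records.
#' @export
write_signature_dir <- function(repo, dir) {
  .assert(is_repository(repo), "repo must be a sig_repository")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- repo_sig_ids(repo)
  for (i in seq_along(ids))
    write_signature_json(repo_signature(repo, ids[i]),
                         file.path(dir, sprintf("sig_%05d.json", i)))
  invisible(dir)
}

#' Read a query signature from a two-column TSV
#'
#' Tab-delimited `gene_id<TAB>z`; an optional single header line is detected
#' by a non-numeric second field. The signature id is derived from the file
#' name.
#'
#' @param path path to the TSV.
#' @param sig_id id for the resulting signature (default: file base name).
#' @return a [signature_record()].
#' @export
read_query_tsv <- function(path, sig_id = NULL) {
  .assert(file.exists(path), "no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 2L, path, ": needs at least 2 data rows")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 2L)
  .assert(length(bad) == 0L,
          path, ": row ", if (length(bad)) bad[1L] else 0L,
          " does not have exactly 2 tab-separated fields")
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(fields[[1L]][2L])))) start <- 2L
  rows <- fields[seq.int(start, length(fields))]
  genes <- vapply(rows, `[[`, character(1), 1L)
  zraw <- vapply(rows, `[[`, character(1), 2L)
  z <- suppressWarnings(as.numeric(zraw))
  bad <- which(is.na(z))
  .assert(length(bad) == 0L,
          path, ": unparseable z value '",
          if (length(bad)) zraw[bad[1L]] else "", "' at data row ",
          if (length(bad)) bad[1L] else 0L)
  dup <- genes[duplicated(genes)]
  .assert(length(dup) == 0L, path, ": duplicated gene id '",
          if (length(dup)) dup[1L] else "", "'")
  if (is.null(sig_id))
    sig_id <- tools::file_path_sans_ext(basename(path))
  signature_record(sig_id, genes, z)
}

#' Write a screen report to disk
#'
#' Emits the ranked per-reference table as TSV and a machine-readable JSON
#' summary (direction, config snapshot, counts, and the top rows).
#'
#' @param report a `screen_report`.
#' @param tsv path for the tab-delimited results table.
#' @param json optional path for the JSON summary.
#' @param top_n how many top rows to embed in the JSON summary.
#' @return `tsv`, invisibly.
#' @export
write_report <- function(report, tsv, json = NULL, top_n = 10L) {
  .assert(inherits(report, "screen_report"), "not a screen_report")
  data.table::fwrite(report$results, tsv, sep = "\t", quote = FALSE,
                     na = "NA")
  if (!is.null(json)) {
    top <- head(report$results, top_n)
    jsonlite::write_json(
      list(direction = report$direction,
           query_id = report$query_id,
           config = unclass(report$config),
           summary = report$summary,
           top = top),
      json, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(tsv)
}

#' Read a screen configuration from YAML or JSON
#'
#' Keys mirror the CLI flags / [screen_config()] arguments. YAML requires
#' the `yaml` package; JSON always works.
#'
#' @param path a `.yaml`/`.yml` or `.json` config file.
#' @return a [screen_config()].
#' @export
read_config <- function(path) {
  .assert(file.exists(path), "no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yaml", "yml")) {
    .assert(requireNamespace("yaml", quietly = TRUE),
            "the 'yaml' package is required for YAML configs; use JSON instead")
    yaml::read_yaml(path)
  } else jsonlite::fromJSON(path, simplifyVector = TRUE)
  known <- names(formals(screen_config))
  unknown <- setdiff(names(vals), known)
  .assert(length(unknown) == 0L, "unknown config keys: ",
          paste(unknown, collapse = ", "))
  do.call(screen_config, vals)
}
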