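#' COLVAR-style window files and gridded PMF text
#'
#' One whitespace-delimited text file per window with a
#' `#! FIELDS time z1 [z2]` header (comment lines start with `#`), plus a
#' metadata file with one `key=value` record line per window
#' (`file`, `center_z1`[, `center_z2`], `kappa`, optionally `n_samples`,
#' `seed`). PMFs are written as `z1 z2 F` triplets, row-major, with a header
#' recording bins, temperature and normalization.
#'
#' @name io
NULL

#' Write umbrella windows to a directory
#'
#' @param windows list of `umbrella_window` objects.
#' @param dir output directory (created if missing).
#' @param metadata name of the metadata file inside `dir`.
#' @return the metadata path, invisibly.
#' @export
write_windows <- function(windows, dir, metadata = "windows.meta") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- ncol(windows[[1]]$samples)
  meta <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    fn <- sprintf("window_%04d.colvar", i)
    con <- file(file.path(dir, fn), "w")
    writeLines(paste("#! FIELDS time", paste(paste0("z", seq_len(d)),
                                             collapse = " ")), con)
    tm <- seq_len(nrow(w$samples))
    writeLines(paste(tm, apply(format(w$samples, digits = 17,
                                      scientific = TRUE, trim = TRUE),
                               1L, paste, collapse = " ")), con)
    close(con)
    kv <- c(paste0("file=", fn),
            paste0("center_z", seq_len(d), "=",
                   format(w$centers, digits = 17, trim = TRUE)),
            paste0("kappa=", format(w$force_constant, digits = 17)),
            paste0("n_samples=", w$n_samples),
            paste0("seed=", w$seed))
    meta[i] <- paste(kv, collapse = " ")
  }
  mpath <- file.path(dir, metadata)
  writeLines(meta, mpath)
  invisible(mpath)
}

.parse_kv_line <- function(line) {
  parts <- strsplit(trimws(line), "\\s+")[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  vals <- vapply(kv, `[`, character(1), 2L)
  names(vals) <- vapply(kv, `[`, character(1), 1L)
  vals
}

#' Read umbrella windows from COLVAR-style files
#'
#' @param dir directory holding the window files.
#' @param metadata metadata file name inside `dir` (or an absolute path).
#' @param column_map optional integer vector mapping CV index to data column
#'   (after the time column), for files whose column order differs from the
#'   writer's dialect.
#' @return list of `umbrella_window` objects.
#' @export
read_windows <- function(dir, metadata = "windows.meta", column_map = NULL) {
  mpath <- if (file.exists(metadata)) metadata else file.path(dir, metadata)
  if (!file.exists(mpath))
    stop("metadata file not found: ", mpath, call. = FALSE)
  lines <- readLines(mpath)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lapply(lines, function(ln) {
    kv <- .parse_kv_line(ln)
    if (!"file" %in% names(kv) || !"kappa" %in% names(kv))
      stop("metadata record missing 'file' or 'kappa': ", ln, call. = FALSE)
    ctr_keys <- grep("^center_z[0-9]+$", names(kv), value = TRUE)
    ctr_keys <- ctr_keys[order(as.integer(sub("center_z", "", ctr_keys)))]
    centers <- as.numeric(kv[ctr_keys])
    d <- length(centers)
    fpath <- file.path(dir, kv[["file"]])
    if (!file.exists(fpath))
      stop("window file not found: ", fpath, call. = FALSE)
    raw <- readLines(fpath)
    keep <- !startsWith(trimws(raw), "#") & nzchar(trimws(raw))
    rows <- raw[keep]
    if (!length(rows))
      stop("window file has no samples: ", fpath, call. = FALSE)
    fields <- strsplit(trimws(rows), "\\s+")
    nf <- lengths(fields)
    if (any(nf != nf[1])) {
      bad <- which(nf != nf[1])[1]
      stop(sprintf("column-count mismatch in %s at line %d (%d vs %d columns)",
                   fpath, which(keep)[bad], nf[bad], nf[1]), call. = FALSE)
    }
    if (nf[1] < d + 1L)
      stop(sprintf("%s has %d columns; need time + %d CVs", fpath, nf[1], d),
           call. = FALSE)
    vals <- matrix(as.numeric(unlist(fields)), ncol = nf[1], byrow = TRUE)
    cols <- if (is.null(column_map)) seq_len(d) + 1L else column_map + 1L
    samples <- vals[, cols, drop = FALSE]
    colnames(samples) <- paste0("z", seq_len(d))
    structure(list(centers = centers,
                   force_constant = as.numeric(kv[["kappa"]]),
                   samples = samples, n_samples = nrow(samples),
                   seed = if ("seed" %in% names(kv))
                     as.integer(kv[["seed"]]) else NA_integer_,
                   temperature = NA_real_, acceptance_rate = NA_real_),
              class = "umbrella_window")
  })
}

#' Write/read a PMF grid as text
#'
#' Row-major `z1 z2 F` triplets (`z F` pairs in 1D); unsampled bins are
#' written as `NA`. The header records the bin counts, temperature and the
#' min-zero normalization.
#'
#' @param pmf a `pmf_grid`.
#' @param file file path.
#' @return `write_pmf` returns `file` invisibly; `read_pmf` a `pmf_grid`
#'   (without counts; sampled bins are those with finite F).
#' @export
write_pmf <- function(pmf, file) {
  con <- file(file, "w")
  nb <- vapply(pmf$axes, function(e) length(e) - 1L, integer(1))
  writeLines(c(
    sprintf("# PMF grid: %s bins", paste(nb, collapse = " x ")),
    sprintf("# temperature_K: %g", pmf$temperature),
    sprintf("# edges_z1: %.17g %.17g", pmf$axes[[1]][1],
            pmf$axes[[1]][length(pmf$axes[[1]])]),
    if (pmf$dim == 2L)
      sprintf("# edges_z2: %.17g %.17g", pmf$axes[[2]][1],
              pmf$axes[[2]][length(pmf$axes[[2]])]),
    "# normalization: min over sampled bins = 0",
    if (pmf$dim == 2L) "# columns: z1 z2 F" else "# columns: z F"), con)
  if (pmf$dim == 2L) {
    grid <- expand.grid(z1 = pmf$midpoints[[1]], z2 = pmf$midpoints[[2]])
    writeLines(sprintf("%.10g %.10g %.10g", grid$z1, grid$z2,
                       as.vector(pmf$free_energy)), con)
  } else {
    writeLines(sprintf("%.10g %.10g", pmf$midpoints[[1]], pmf$free_energy),
               con)
  }
  close(con)
  invisible(file)
}

#' @rdname write_pmf
#' @export
read_pmf <- function(file) {
  raw <- readLines(file)
  hdr <- raw[startsWith(raw, "#")]
  body <- raw[!startsWith(raw, "#") & nzchar(trimws(raw))]
  tK <- as.numeric(sub(".*temperature_K: *", "",
                       grep("temperature_K", hdr, value = TRUE)[1]))
  ## unsampled bins are written as the literal "NA"
  vals <- do.call(rbind, lapply(strsplit(trimws(body), "\\s+"), function(x)
    suppressWarnings(as.numeric(x))))
  d <- ncol(vals) - 1L
  mids <- lapply(seq_len(d), function(dd) sort(unique(vals[, dd])))
  nb <- lengths(mids)
  Fv <- vals[, d + 1L]
  key <- vals[, 1]
  if (d == 2L) {
    ord <- order(match(vals[, 2], mids[[2]]), match(vals[, 1], mids[[1]]))
    Fm <- matrix(Fv[ord], nb[1], nb[2])
  } else {
    Fm <- Fv[order(key)]
  }
  axes <- lapply(mids, function(m) {
    h <- if (length(m) > 1L) m[2] - m[1] else 1
    c(m - h / 2, m[length(m)] + h / 2)
  })
  counts <- ifelse(is.na(Fm), 0L, 1L)
  .new_pmf_grid(axes, Fm, counts, prob = NULL, temperature = tK)
}

#' Write WHAM window offsets sidecar
#'
#' @param fit a `wham_fit`.
#' @param file file path.
#' @return `file`, invisibly.
#' @export
write_offsets <- function(fit, file) {
  utils::write.csv(data.frame(window = seq_along(fit$offsets),
                              offset_kJmol = fit$offsets),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
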