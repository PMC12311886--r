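#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses `BEGIN IONS`/`END IONS` blocks. `PEPMASS` (first token) becomes the
#' precursor m/z; polarity is taken from an explicit `IONMODE` (or `ION_MODE`
#' / `IONSMODE`) field if present, otherwise from the sign of `CHARGE`; a block
#' with neither is an error. `TITLE` becomes the spectrum id (falling back to
#' `spectrum_<k>`); every other `KEY=value` line is kept in `metadata`.
#'
#' Peak lines are `mz intensity` pairs separated by whitespace. Peaks are
#' re-sorted by ascending m/z if the file is unsorted; blocks with zero peaks
#' are skipped with a warning; malformed blocks raise an error naming the
#' block index.
#'
#' @param path Path to an MGF file.
#' @return A list of [spectrum] objects.
#' @seealso [write_mgf()]
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) != length(end) || any(end < begin)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS", call. = FALSE)
  }
  out <- vector("list", length(begin))
  kept <- logical(length(begin))
  for (k in seq_along(begin)) {
    body <- lines[seq(begin[k] + 1L, end[k] - 1L)]
    body <- body[nzchar(body)]
    is_kv <- grepl("=", body, fixed = TRUE)
    kv <- body[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    pk <- body[!is_kv]
    if (!length(pk)) {
      warning("MGF block ", k, " has zero peaks; skipped", call. = FALSE)
      next
    }
    fields <- strsplit(pk, "[ \t]+")
    if (any(lengths(fields) < 2)) {
      stop("malformed peak line in MGF block ", k, call. = FALSE)
    }
    mz <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
    int <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    if (anyNA(mz) || anyNA(int)) {
      stop("non-numeric peak values in MGF block ", k, call. = FALSE)
    }
    if (!"PEPMASS" %in% keys) {
      stop("missing PEPMASS in MGF block ", k, call. = FALSE)
    }
    pep <- suppressWarnings(as.numeric(strsplit(vals[match("PEPMASS", keys)],
                                                "[ \t]+")[[1]][1]))
    if (is.na(pep)) stop("invalid PEPMASS in MGF block ", k, call. = FALSE)
    ionmode_keys <- c("IONMODE", "ION_MODE", "IONSMODE")
    polarity <- NULL
    im <- match(ionmode_keys, keys)
    im <- im[!is.na(im)]
    if (length(im)) {
      v <- tolower(vals[im[1]])
      polarity <- if (startsWith(v, "p")) "positive" else if (startsWith(v, "n"))
        "negative" else stop("unrecognized ion mode in MGF block ", k, call. = FALSE)
    } else if ("CHARGE" %in% keys) {
      polarity <- if (grepl("-", vals[match("CHARGE", keys)], fixed = TRUE))
        "negative" else "positive"
    } else {
      stop("cannot infer polarity in MGF block ", k,
           ": no IONMODE or CHARGE field", call. = FALSE)
    }
    id <- if ("TITLE" %in% keys) vals[match("TITLE", keys)] else
      sprintf("spectrum_%d", k)
    meta_keys <- setdiff(keys, c("PEPMASS", "CHARGE", "TITLE", ionmode_keys))
    metadata <- as.list(vals[match(meta_keys, keys)])
    names(metadata) <- meta_keys
    out[[k]] <- spectrum(mz = mz, intensity = int, precursor_mz = pep,
                         polarity = polarity, id = id, metadata = metadata)
    kept[k] <- TRUE
  }
  out[kept]
}

#' Write spectra to an MGF file
#'
#' Emits one `BEGIN IONS` block per spectrum with `TITLE`, `PEPMASS`,
#' `CHARGE` and `IONMODE` fields. Numbers are written with 12 significant
#' digits so that a read/write round trip is lossless well below 1e-9.
#'
#' @param spectra A list of [spectrum] objects (may be empty).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  fmt <- function(x) sprintf("%.12g", x)
  blocks <- vapply(spectra, function(s) {
    validate_spectrum(s)
    paste(c("BEGIN IONS",
            paste0("TITLE=", s$id),
            paste0("PEPMASS=", fmt(s$precursor_mz)),
            paste0("CHARGE=1", if (s$polarity == "negative") "-" else "+"),
            paste0("IONMODE=", s$polarity),
            paste(fmt(s$mz), fmt(s$intensity)),
            "END IONS", ""),
          collapse = "\n")
  }, "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n")
  invisible(path)
}

#' Read an explained-ion sidecar table
#'
#' The sidecar is a TSV with columns `spectrum_id`, `mz`, `explained` (0/1),
#' typically exported from an external fragmentation-tree tool that flags
#' which fragment ions are structurally explainable.
#'
#' @param path Path to the TSV file.
#' @return A data frame with the three columns.
#' @seealso [attach_explained()], [write_explained()]
#' @export
read_explained <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("spectrum_id", "mz", "explained")
  if (!all(need %in% names(tab))) {
    stop("explained sidecar must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  tab$explained <- as.logical(as.integer(tab$explained))
  tab[need]
}

#' Write the explained-ion flags of spectra to a sidecar TSV
#'
#' @param spectra A list of [spectrum] objects carrying `explained` flags
#'   (spectra without flags are skipped).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_explained <- function(spectra, path) {
  rows <- lapply(spectra, function(s) {
    if (is.null(s$explained)) return(NULL)
    data.frame(spectrum_id = s$id, mz = sprintf("%.12g", s$mz),
               explained = as.integer(s$explained))
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(spectrum_id = character(),
                                      mz = character(), explained = integer())
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach explained-ion flags from a sidecar table to spectra
#'
#' Rows are matched to peaks by `spectrum_id` and by m/z within `tol`.
#' Spectra with no rows in the table are left unannotated; annotated spectra
#' get `explained = FALSE` for unlisted peaks.
#'
#' @param spectra A list of [spectrum] objects.
#' @param table A data frame as returned by [read_explained()].
#' @param tol m/z matching tolerance in Da (default 1e-4).
#' @return The list of spectra with `explained` flags filled in.
#' @export
attach_explained <- function(spectra, table, tol = 1e-4) {
  table$mz <- as.numeric(table$mz)
  by_id <- split(table, table$spectrum_id)
  lapply(spectra, function(s) {
    rows <- by_id[[s$id]]
    if (is.null(rows)) return(s)
    expl <- logical(length(s$mz))
    for (i in which(rows$explained)) {
      j <- which(abs(s$mz - rows$mz[i]) <= tol)
      if (length(j)) expl[j[which.min(abs(s$mz[j] - rows$mz[i]))]] <- TRUE
    }
    s$explained <- expl
    s
  })
}
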