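## Plain-text interchange formats. Traces: TSV columns t_us, intensity;
## spectra: TSV columns offset_khz, intensity. Both carry "# key: value"
## metadata header lines; readers tolerate blank lines and extra comments,
## writers emit 6 significant digits.

read_kv_header <- function(lines) {
  kv <- list()
  hdr <- grep("^#", lines, value = TRUE)
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      kv[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  kv
}

read_tsv_body <- function(path, col_names) {
  lines <- readLines(path)
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  df <- utils::read.table(text = body, header = TRUE, sep = "\t")
  if (!all(col_names %in% names(df))) {
    stop("expected columns ", paste(col_names, collapse = ", "),
         " in ", path, call. = FALSE)
  }
  list(df = df, meta = read_kv_header(lines))
}

fmt6 <- function(x) formatC(x, digits = 6, format = "g")

write_kv_header <- function(con, kv) {
  for (k in names(kv)) {
    v <- kv[[k]]
    if (is.null(v) || (length(v) == 1 && is.na(v))) next
    writeLines(sprintf("# %s: %s", k,
                       if (is.numeric(v)) fmt6(v) else as.character(v)), con)
  }
}

#' Read a time-domain trace file
#'
#' TSV with columns `t_us`, `intensity` and `# key: value` header lines
#' (`kind`, `temperature_K`, `nucleus`, `rf_offset_khz`).
#'
#' @param path File path.
#' @return An [endor_trace()].
#' @export
read_trace <- function(path) {
  r <- read_tsv_body(path, c("t_us", "intensity"))
  m <- r$meta
  endor_trace(r$df$t_us * 1e-6, r$df$intensity,
              kind = if (is.null(m$kind)) "nse" else m$kind,
              temperature = if (is.null(m$temperature_K)) NA_real_
                            else m$temperature_K,
              nucleus = if (is.null(m$nucleus)) NA_character_ else m$nucleus,
              rf_offset = if (is.null(m$rf_offset_khz)) NA_real_
                          else m$rf_offset_khz * 1e3)
}

#' Write a time-domain trace file
#'
#' @param trace An [endor_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "endor_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  write_kv_header(con, list(
    kind = trace$meta$kind, temperature_K = trace$meta$temperature,
    nucleus = trace$meta$nucleus,
    rf_offset_khz = if (is.null(trace$meta$rf_offset) ||
                        is.na(trace$meta$rf_offset)) NULL
                    else trace$meta$rf_offset / 1e3
  ))
  writeLines("t_us\tintensity", con)
  writeLines(paste(fmt6(trace$t * 1e6), fmt6(trace$I), sep = "\t"), con)
  invisible(path)
}

#' Read an ENDOR spectrum file
#'
#' TSV with columns `offset_khz`, `intensity` and `# key: value` header lines
#' (`nucleus`, `tau_ns`, `temperature_K`, `nu_ref_mhz`).
#'
#' @param path File path.
#' @return An [endor_spectrum()].
#' @export
read_spectrum <- function(path) {
  r <- read_tsv_body(path, c("offset_khz", "intensity"))
  m <- r$meta
  meta <- list(
    nucleus = if (is.null(m$nucleus)) NA_character_ else m$nucleus,
    tau = if (is.null(m$tau_ns)) NA_real_ else m$tau_ns * 1e-9,
    temperature = if (is.null(m$temperature_K)) NA_real_ else m$temperature_K,
    nu_ref = if (is.null(m$nu_ref_mhz)) NA_real_ else m$nu_ref_mhz * 1e6
  )
  endor_spectrum(r$df$offset_khz * 1e3, r$df$intensity, meta = meta)
}

#' Write an ENDOR spectrum file
#'
#' @param spectrum An [endor_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "endor_spectrum"))
  m <- spectrum$meta
  con <- file(path, "w")
  on.exit(close(con))
  write_kv_header(con, list(
    nucleus = m$nucleus,
    tau_ns = if (is.null(m$tau)) NULL else m$tau * 1e9,
    temperature_K = m$temperature,
    nu_ref_mhz = if (is.null(m$nu_ref)) NULL else m$nu_ref / 1e6
  ))
  writeLines("offset_khz\tintensity", con)
  writeLines(paste(fmt6(spectrum$offsets / 1e3), fmt6(spectrum$intensities),
                   sep = "\t"), con)
  invisible(path)
}
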