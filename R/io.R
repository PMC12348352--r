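# File I/O: field-scan CSV round trips, gnuplot-style grid text, string and
# PMF CSV exports, and JSON summaries with a config-hash sidecar. All
# formats are plain text.

.FIELD_SCAN_HEADER <- c("axis", "sign", "strength_Vm", "quantity", "value",
                        "units", "phase", "seed")

#' Write a field-scan table to CSV
#'
#' @param table A field-scan table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_field_scan <- function(table, path) {
  table <- as.data.frame(table)
  stopifnot(all(.FIELD_SCAN_HEADER %in% names(table)))
  ord <- c(.FIELD_SCAN_HEADER, setdiff(names(table), .FIELD_SCAN_HEADER))
  out <- table[, ord]
  # full-precision doubles so that write -> read is an exact round trip
  for (col in names(out))
    if (is.double(out[[col]])) out[[col]] <- sprintf("%.17g", out[[col]])
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a field-scan table from CSV
#'
#' Tolerant reader: the canonical columns are required (missing ones are an
#' error), extra columns are preserved with a warning, and a non-numeric
#' strength column is an error.
#'
#' @param path CSV file with the field-scan header.
#' @return Data frame of class `"field_scan"`.
#' @export
read_field_scan <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty field-scan file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.FIELD_SCAN_HEADER, names(tab))
  if (length(missing_cols))
    stop("missing field-scan columns: ", paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(tab), .FIELD_SCAN_HEADER)
  if (length(extra))
    warning("extra field-scan columns preserved: ",
            paste(extra, collapse = ", "))
  if (!is.numeric(tab$strength_Vm))
    stop("strength_Vm must be numeric")
  class(tab) <- c("field_scan", "data.frame")
  tab
}

#' Write a 2-D free-energy grid as gnuplot-style text
#'
#' One `phi psi F` row per node, with a blank line between phi blocks.
#'
#' @param grid An `fe_grid` from [landscape_grid()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_grid <- function(grid, path) {
  stopifnot(inherits(grid, "fe_grid"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(grid$phi)) {
    writeLines(sprintf("%.6g %.6g %.10g", grid$phi[i], grid$psi,
                       grid$F[i, ]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Write the string trajectory of an FTS run
#'
#' CSV with columns `iteration,image,phi,psi`; iteration 0 is the initial
#' string.
#'
#' @param result An `fts_result`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_string_csv <- function(result, path) {
  stopifnot(inherits(result, "fts_result"))
  rows <- lapply(seq_along(result$string_history), function(k) {
    im <- result$string_history[[k]]$images
    data.frame(iteration = k - 1L, image = seq_len(nrow(im)) - 1L,
               phi = im[, 1], psi = im[, 2])
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a PMF profile to CSV
#'
#' @param profile A `pmf_profile`.
#' @param path Output file (columns `alpha,F_kJmol`).
#' @return `path`, invisibly.
#' @export
write_pmf_csv <- function(profile, path) {
  stopifnot(inherits(profile, "pmf_profile"))
  df <- data.frame(alpha = profile$alpha, F_kJmol = profile$F)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# FNV-1a 32-bit hash of a string, returned as hex. A provenance checksum
# for config sidecars, not a cryptographic hash. Arithmetic is done in
# doubles modulo 2^32 (split multiply keeps every product under 2^53).
.fnv1a <- function(s) {
  mulmod32 <- function(a, b) {
    al <- a %% 65536; ah <- a %/% 65536
    (al * b + ((ah * b) %% 65536) * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in as.integer(charToRaw(s))) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)  # xor folds into the low byte
    h <- mulmod32(h, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a JSON summary with a config-hash sidecar entry
#'
#' Serializes `x` to pretty JSON, embedding `config_hash` (a checksum of the
#' canonical JSON of `config`) so any two artifacts from the same resolved
#' configuration can be matched.
#'
#' @param x Named list to serialize.
#' @param path Output JSON file.
#' @param config Resolved configuration list (hashed into the summary).
#' @return `path`, invisibly.
#' @export
write_json_summary <- function(x, path, config = NULL) {
  if (!is.null(config))
    x$config_hash <- .fnv1a(jsonlite::toJSON(config, auto_unbox = TRUE))
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
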