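# Minimal FCS3.0 input/output.
#
# Profile: one dataset per file, HEADER + TEXT + DATA segments, list mode,
# 32-bit floating point ("F") or 32-bit integer ("I") data, little- or
# big-endian, no analysis segment. This matches the file layout produced by
# bench cytometers operating in list mode and is sufficient for lossless
# round-tripping of event tables.

#' Default canonical-to-instrument channel-name mapping
#'
#' Maps the canonical channel roles (`FSC`, `SSC`, `GFP`, `RFP`) to
#' instrument parameter names (`$PnN`) in the style of a bench cytometer with
#' linear height signals.
#'
#' @return A named character vector (names are canonical roles).
#' @export
default_channel_names <- function() {
  c(FSC = "FSC-HLin", SSC = "SSC-HLin", GFP = "GRN-B-HLin", RFP = "YEL-B-HLin")
}

#' Write an event table to a minimal FCS3.0 file
#'
#' Emits an FCS3.0 file (HEADER with segment offsets; TEXT with `$DATATYPE`,
#' `$BYTEORD`, `$PAR`, `$PnN`, `$TOT` and companions; DATA as 32-bit values in
#' list mode) that [read_fcs()] round-trips bit-exactly for floating-point
#' data. Ground-truth columns (`transfected`, `debris`) and any column not in
#' the channel mapping are not written.
#'
#' @param events A data frame with one column per canonical channel named in
#'   `channel_names` (default `FSC`, `SSC`, `GFP`, `RFP`).
#' @param path Output file path.
#' @param channel_names Named character vector mapping canonical channel
#'   roles to the `$PnN` parameter names written to the file.
#' @param datatype `"F"` (32-bit float, default) or `"I"` (32-bit integer;
#'   values are rounded).
#' @param byte_order `"little"` (default) or `"big"`.
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path,
                      channel_names = default_channel_names(),
                      datatype = c("F", "I"),
                      byte_order = c("little", "big")) {
  datatype <- match.arg(datatype)
  byte_order <- match.arg(byte_order)
  if (is.null(names(channel_names)) || any(names(channel_names) == "")) {
    abort("`channel_names` must be a fully named character vector.")
  }
  missing_cols <- setdiff(names(channel_names), names(events))
  if (length(missing_cols) > 0) {
    abort(sprintf(
      "`events` is missing mapped channel column(s): %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }

  mat <- as.matrix(as.data.frame(events)[, names(channel_names), drop = FALSE])
  storage.mode(mat) <- "double"
  n_tot <- nrow(mat)
  n_par <- ncol(mat)
  byteord <- if (byte_order == "little") "1,2,3,4" else "4,3,2,1"
  endian <- byte_order

  keywords <- c(
    "$BEGINANALYSIS" = "0", "$ENDANALYSIS" = "0",
    "$BEGINSTEXT" = "0", "$ENDSTEXT" = "0",
    "$BYTEORD" = byteord,
    "$DATATYPE" = datatype,
    "$MODE" = "L",
    "$NEXTDATA" = "0",
    "$TOT" = as.character(n_tot),
    "$PAR" = as.character(n_par)
  )
  for (i in seq_len(n_par)) {
    keywords[sprintf("$P%dN", i)] <- unname(channel_names[i])
    keywords[sprintf("$P%dB", i)] <- "32"
    keywords[sprintf("$P%dE", i)] <- "0,0"
    keywords[sprintf("$P%dR", i)] <- "4294967296"
  }

  delim <- "/"
  build_text <- function(begin_data, end_data) {
    kw <- c(keywords,
            "$BEGINDATA" = as.character(begin_data),
            "$ENDDATA" = as.character(end_data))
    paste0(delim, paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  }

  header_len <- 58L
  data_len <- n_tot * n_par * 4L
  # The TEXT segment embeds the DATA offsets, whose digit count depends on
  # the TEXT length; iterate to a fixed point (converges in <= 3 passes).
  begin_data <- 0L
  end_data <- 0L
  for (pass in 1:5) {
    text <- build_text(begin_data, end_data)
    new_begin <- header_len + nchar(text, type = "bytes")
    new_end <- if (data_len > 0) new_begin + data_len - 1L else 0L
    if (new_begin == begin_data && new_end == end_data) break
    begin_data <- new_begin
    end_data <- new_end
  }
  text <- build_text(begin_data, end_data)
  text_start <- header_len
  text_end <- text_start + nchar(text, type = "bytes") - 1L

  off <- function(x) formatC(x, width = 8, flag = " ")
  # DATA offsets above 99,999,999 bytes do not fit the 8-character header
  # fields; FCS3.0 then zeroes them and relies on $BEGINDATA/$ENDDATA.
  hdr_begin <- if (begin_data <= 99999999) begin_data else 0L
  hdr_end <- if (end_data <= 99999999) end_data else 0L
  header <- paste0(
    "FCS3.0    ",
    off(text_start), off(text_end),
    off(hdr_begin), off(hdr_end),
    off(0), off(0)
  )

  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeChar(header, con, eos = NULL, useBytes = TRUE)
  writeChar(text, con, eos = NULL, useBytes = TRUE)
  if (n_tot > 0) {
    values <- as.vector(t(mat))
    if (datatype == "I") {
      writeBin(as.integer(round(values)), con, size = 4L, endian = endian)
    } else {
      writeBin(values, con, size = 4L, endian = endian)
    }
  }
  invisible(path)
}

#' Read a minimal FCS3.0 file into an event table
#'
#' Parses the HEADER and TEXT segments, honours `$DATATYPE` (`F` or `I`),
#' `$BYTEORD` (both orders) and 32-bit `$PnB`, and resolves canonical channel
#' roles through a name map applied to the `$PnN` parameter names.
#'
#' @param path Path to an FCS3.0 file.
#' @param channel_names Named character vector mapping canonical roles to
#'   `$PnN` names (default [default_channel_names()]). Mapped parameters are
#'   renamed to their canonical role in the returned table; unmapped
#'   parameters keep their `$PnN` name.
#' @return A tibble with one row per event; attribute `fcs_keywords` carries
#'   the TEXT segment key-value pairs.
#' @export
read_fcs <- function(path, channel_names = default_channel_names()) {
  if (!file.exists(path)) {
    abort(sprintf("FCS file not found: %s", path))
  }
  raw <- readBin(path, what = "raw", n = file.info(path)$size)
  if (length(raw) < 58) {
    abort("File too short to contain an FCS3.0 header.")
  }
  version <- rawToChar(raw[1:6])
  if (!identical(version, "FCS3.0")) {
    abort(sprintf("Not an FCS3.0 file (version field '%s').", version))
  }
  header_field <- function(i) {
    start <- 10L + (i - 1L) * 8L + 1L
    as.integer(trimws(rawToChar(raw[start:(start + 7L)])))
  }
  text_start <- header_field(1)
  text_end <- header_field(2)
  data_start <- header_field(3)
  data_end <- header_field(4)
  if (is.na(text_start) || is.na(text_end) || text_end <= text_start) {
    abort("Malformed FCS header: invalid TEXT segment offsets.")
  }

  text <- rawToChar(raw[(text_start + 1L):(text_end + 1L)])
  delim <- substr(text, 1L, 1L)
  parts <- strsplit(substring(text, 2L), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2L != 0L) {
    # trailing delimiter produces an even split; a stray empty tail is fine
    parts <- parts[seq_len(length(parts) - length(parts) %% 2L)]
  }
  keys <- parts[seq(1, length(parts), by = 2)]
  vals <- parts[seq(2, length(parts), by = 2)]
  kw <- setNames(vals, keys)

  need <- function(key) {
    if (!key %in% names(kw)) abort(sprintf("TEXT segment missing %s.", key))
    kw[[key]]
  }
  n_tot <- as.integer(need("$TOT"))
  n_par <- as.integer(need("$PAR"))
  datatype <- need("$DATATYPE")
  if (!datatype %in% c("F", "I")) {
    abort(sprintf("Unsupported $DATATYPE '%s' (only F and I).", datatype))
  }
  byteord <- need("$BYTEORD")
  endian <- switch(byteord,
    "1,2,3,4" = "little",
    "4,3,2,1" = "big",
    abort(sprintf("Unsupported $BYTEORD '%s'.", byteord))
  )
  pnn <- vapply(seq_len(n_par), function(i) need(sprintf("$P%dN", i)), "")
  pnb <- vapply(seq_len(n_par), function(i) need(sprintf("$P%dB", i)), "")
  if (!all(pnb == "32")) {
    abort("Only 32-bit parameters ($PnB = 32) are supported.")
  }

  if (is.na(data_start) || data_start == 0L) {
    data_start <- as.integer(need("$BEGINDATA"))
    data_end <- as.integer(need("$ENDDATA"))
  }

  if (n_tot > 0) {
    n_values <- n_tot * n_par
    con <- rawConnection(raw[(data_start + 1L):(data_end + 1L)])
    on.exit(close(con), add = TRUE)
    values <- if (datatype == "F") {
      readBin(con, what = "double", n = n_values, size = 4L, endian = endian)
    } else {
      as.double(readBin(con, what = "integer", n = n_values, size = 4L,
                        endian = endian))
    }
    mat <- matrix(values, ncol = n_par, byrow = TRUE)
  } else {
    mat <- matrix(numeric(0), ncol = n_par)
  }
  colnames(mat) <- pnn
  out <- as_tibble(mat)

  if (!is.null(channel_names)) {
    missing_ch <- setdiff(unname(channel_names), pnn)
    if (length(missing_ch) > 0) {
      abort(sprintf(
        "Cannot resolve channel(s) %s; available $PnN names: %s.",
        paste(missing_ch, collapse = ", "),
        paste(pnn, collapse = ", ")
      ))
    }
    idx <- match(unname(channel_names), names(out))
    names(out)[idx] <- names(channel_names)
  }
  attr(out, "fcs_keywords") <- kw
  out
}

#' Quantize doubles to 32-bit float precision
#'
#' FCS DATA segments store 32-bit floats; this applies the same precision
#' loss in memory, so that `as_float32(x)` equals the values recovered by
#' [read_fcs()] after [write_fcs()] exactly.
#'
#' @param x Numeric vector.
#' @return Numeric vector quantized to single precision.
#' @export
as_float32 <- function(x) {
  readBin(writeBin(as.double(x), raw(), size = 4L), what = "double",
          n = length(x), size = 4L)
}
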