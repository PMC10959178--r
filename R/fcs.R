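# Minimal FCS 3.0/3.1 list-mode reader. Only what the calcium-flux pipeline
# needs: HEADER offsets, TEXT keyword segment, uncompensated list-mode DATA
# of a single homogeneous datatype (F = float32, D = float64, I = unsigned
# integer with byte widths that are multiples of 8 bits), little- or
# big-endian byte order, and TIME tick conversion via $TIMESTEP.

parse_fcs_text <- function(raw_text) {
  delim <- rawToChar(raw_text[1L])
  body <- rawToChar(raw_text[-1L])
  # FCS escapes a literal delimiter by doubling it; the simple split below is
  # sufficient for instrument files that avoid literal delimiters in values
  parts <- strsplit(body, delim, fixed = TRUE)[[1]]
  parts <- parts[!(seq_along(parts) > length(parts) - 1L & parts == "")]
  if (length(parts) %% 2L == 1L) parts <- parts[-length(parts)]
  keys <- toupper(trimws(parts[seq(1L, length(parts), by = 2L)]))
  vals <- parts[seq(2L, length(parts), by = 2L)]
  stats::setNames(as.list(vals), keys)
}

#' Read a calcium-flux series from an FCS 3.0/3.1 file
#'
#' Parses standard list-mode FCS as produced by cytometers such as the LSRII
#' or Aurora: header offsets, TEXT keywords and a single DATA segment of
#' float (`$DATATYPE` F or D) or unsigned-integer (I) events. The TIME
#' parameter is converted to seconds with the file's `$TIMESTEP` keyword.
#' Events with non-positive Indo-1 channels are dropped and counted, as in
#' [read_flux_csv()].
#'
#' @param path Path to the FCS file.
#' @param channel_map Named list mapping semantic channels to detector names
#'   (`$PnN`), e.g. `list(time = "Time", ch405 = "Indo1-Violet",
#'   ch485 = "Indo1-Blue", gfp = "FITC-A", dtomato = "PE-A",
#'   viability = "APC-Cy7-A")`. `time`, `ch405`, `ch485` and `gfp` are
#'   required; `dtomato` and `viability` are optional.
#' @param sample_id,replicate Metadata for the returned series; `sample_id`
#'   defaults to the `$FIL` keyword or the file name.
#' @return A [flux_series()].
#' @export
read_fcs <- function(path, channel_map, sample_id = NULL, replicate = 1L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  required <- c("time", "ch405", "ch485", "gfp")
  missing_map <- setdiff(required, names(channel_map))
  if (length(missing_map) > 0L) {
    stop("channel_map is missing required channel(s): ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }

  con <- file(path, "rb")
  on.exit(close(con))
  header <- readChar(con, 58L, useBytes = TRUE)
  version <- substr(header, 1L, 6L)
  if (!version %in% c("FCS3.0", "FCS3.1")) {
    stop("unsupported FCS version: ", version, call. = FALSE)
  }
  off <- function(a, b) as.numeric(trimws(substr(header, a, b)))
  text_begin <- off(11L, 18L); text_end <- off(19L, 26L)
  data_begin <- off(27L, 34L); data_end <- off(35L, 42L)

  seek(con, text_begin)
  kw <- parse_fcs_text(readBin(con, "raw", text_end - text_begin + 1L))
  get_kw <- function(key, default = NULL) {
    if (!is.null(kw[[key]])) kw[[key]] else default
  }
  if (data_begin == 0 || data_end == 0) {
    data_begin <- as.numeric(get_kw("$BEGINDATA"))
    data_end <- as.numeric(get_kw("$ENDDATA"))
  }

  if (toupper(get_kw("$MODE", "L")) != "L") {
    stop("only list-mode ($MODE L) FCS data are supported", call. = FALSE)
  }
  n_par <- as.integer(get_kw("$PAR"))
  n_tot <- as.integer(get_kw("$TOT"))
  datatype <- toupper(get_kw("$DATATYPE"))
  byteord <- get_kw("$BYTEORD", "1,2,3,4")
  endian <- if (startsWith(byteord, "1")) "little" else "big"
  par_names <- vapply(seq_len(n_par),
                      function(i) get_kw(sprintf("$P%dN", i), ""), "")
  bits <- vapply(seq_len(n_par),
                 function(i) as.integer(get_kw(sprintf("$P%dB", i), "32")),
                 integer(1))

  seek(con, data_begin)
  n_values <- n_par * n_tot
  if (datatype == "F") {
    if (any(bits != 32L)) stop("float data must be 32-bit", call. = FALSE)
    values <- readBin(con, "numeric", n = n_values, size = 4L, endian = endian)
  } else if (datatype == "D") {
    if (any(bits != 64L)) stop("double data must be 64-bit", call. = FALSE)
    values <- readBin(con, "numeric", n = n_values, size = 8L, endian = endian)
  } else if (datatype == "I") {
    if (length(unique(bits)) != 1L || !bits[1] %in% c(8L, 16L, 32L)) {
      stop("integer data must have uniform 8/16/32-bit parameters",
           call. = FALSE)
    }
    values <- readBin(con, "integer", n = n_values, size = bits[1] / 8L,
                      signed = bits[1] < 32L, endian = endian)
    values[values < 0] <- values[values < 0] + 2^32  # 32-bit wraparound
  } else {
    stop("unsupported $DATATYPE: ", datatype, call. = FALSE)
  }
  if (length(values) != n_values) {
    stop("truncated DATA segment: expected ", n_values, " values, read ",
         length(values), call. = FALSE)
  }
  mat <- matrix(values, ncol = n_par, byrow = TRUE)
  colnames(mat) <- par_names

  pick <- function(channel) {
    det <- channel_map[[channel]]
    if (is.null(det)) return(NULL)
    idx <- match(det, par_names)
    if (is.na(idx)) {
      stop(sprintf("channel `%s` maps to detector '%s' not present in file",
                   channel, det), call. = FALSE)
    }
    mat[, idx]
  }

  timestep <- as.numeric(get_kw("$TIMESTEP", "1"))
  data <- data.frame(time_s = pick("time") * timestep,
                     ch405 = pick("ch405"),
                     ch485 = pick("ch485"),
                     gfp = pick("gfp"))
  for (opt in c("dtomato", "viability")) {
    v <- pick(opt)
    if (!is.null(v)) data[[opt]] <- v
  }
  if (is.null(sample_id)) {
    sample_id <- get_kw("$FIL", sub("\\.fcs$", "", basename(path),
                                    ignore.case = TRUE))
  }
  flux_series(data, sample_id = sample_id, replicate = replicate)
}
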