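# Minimal FCS writer used only to build test fixtures in code (binary files
# are never stored in the repository).
write_test_fcs <- function(path, mat, timestep = NULL, version = "FCS3.0",
                           datatype = "F", endian = "little") {
  n_par <- ncol(mat)
  n_tot <- nrow(mat)
  bits <- switch(datatype, F = 32L, D = 64L, I = 16L)
  kw <- c("$MODE" = "L", "$DATATYPE" = datatype,
          "$BYTEORD" = if (endian == "little") "1,2,3,4" else "4,3,2,1",
          "$PAR" = as.character(n_par), "$TOT" = as.character(n_tot))
  for (i in seq_len(n_par)) {
    kw[sprintf("$P%dN", i)] <- colnames(mat)[i]
    kw[sprintf("$P%dB", i)] <- as.character(bits)
    kw[sprintf("$P%dR", i)] <- "262144"
    kw[sprintf("$P%dE", i)] <- "0,0"
  }
  if (!is.null(timestep)) kw["$TIMESTEP"] <- as.character(timestep)

  delim <- "/"
  text <- paste0(delim,
                 paste0(names(kw), delim, unname(kw), delim, collapse = ""))
  text_begin <- 58L
  text_end <- text_begin + nchar(text) - 1L
  data_begin <- text_end + 1L
  data_end <- data_begin + n_par * n_tot * (bits / 8L) - 1L
  header <- sprintf("%-6s    %8d%8d%8d%8d%8d%8d", version,
                    text_begin, text_end, data_begin, data_end, 0L, 0L)
  stopifnot(nchar(header) == 58L)

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(text, con, eos = NULL)
  values <- as.vector(t(mat))
  if (datatype == "I") {
    writeBin(as.integer(values), con, size = 2L, endian = endian)
  } else {
    writeBin(as.numeric(values), con, size = bits / 8L, endian = endian)
  }
  invisible(path)
}

# small deterministic event table fixture
make_event_df <- function(n = 120, seed = 42) {
  set.seed(seed)
  data.frame(time_s = sort(runif(n, 0, 630)),
             ch405 = rlnorm(n, log(1000), 0.2),
             ch485 = rlnorm(n, log(1000), 0.2),
             gfp = rlnorm(n, log(5000), 0.3),
             dtomato = rlnorm(n, log(3000), 0.3))
}
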