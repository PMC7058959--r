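#' Write / read haplotype samples in ms format
#'
#' The classic Hudson `ms` dialect: a header comment recording the sample
#' layout, then per replicate a `//` separator, `segsites: S`, a
#' `positions:` line giving site coordinates as fractions of the locus with
#' 6 decimals, and one 0/1 character string per haplotype (selected
#' population first, then the neutral population). `read_ms()` inverts
#' `write_ms()` exactly: `read_ms(write_ms(m)) == m`.
#'
#' @param matrices A `hap_matrix` or list of them (multiple ms replicates).
#' @param path File path (or connection) to write to / read from.
#' @return `write_ms()` returns `path` invisibly. `read_ms()` returns a
#'   `hap_matrix` if the file holds a single replicate, otherwise a list.
#' @export
write_ms <- function(matrices, path) {
  if (inherits(matrices, "hap_matrix")) matrices <- list(matrices)
  m1 <- matrices[[1L]]
  out <- c(sprintf("# polysweep ms: n1=%d n2=%d k=%d L=%.17g",
                   m1$n1, m1$n2, m1$k, m1$L))
  for (m in matrices) {
    S <- ncol(m$mat)
    out <- c(out, "//", sprintf("segsites: %d", S))
    if (S > 0) {
      out <- c(out,
               paste("positions:",
                     paste(sprintf("%.6f", m$positions / m$L), collapse = " ")),
               apply(m$mat, 1L, paste, collapse = ""))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_ms
#' @export
read_ms <- function(path) {
  lines <- readLines(path)
  hdr <- regmatches(lines[1L],
                    regexec("n1=(\\d+) n2=(\\d+) k=(\\d+) L=([0-9.eE+-]+)",
                            lines[1L]))[[1L]]
  if (length(hdr) != 5L) {
    stop("line 1: missing or malformed polysweep ms header")
  }
  n1 <- as.integer(hdr[2L]); n2 <- as.integer(hdr[3L])
  k <- as.integer(hdr[4L]); L <- as.numeric(hdr[5L])
  n_hap <- n1 + n2
  recs <- list()
  i <- 2L
  while (i <= length(lines)) {
    if (lines[i] != "//") stop("line ", i, ": expected '//' record separator")
    i <- i + 1L
    if (i > length(lines) || !startsWith(lines[i], "segsites:")) {
      stop("line ", i, ": expected 'segsites:'")
    }
    S <- as.integer(sub("^segsites:\\s*", "", lines[i]))
    if (is.na(S)) stop("line ", i, ": unparseable segsites count")
    i <- i + 1L
    if (S == 0L) {
      recs[[length(recs) + 1L]] <-
        new_hap_matrix(matrix(0L, n_hap, 0), numeric(0), n1, n2, k, L)
      next
    }
    if (i > length(lines) || !startsWith(lines[i], "positions:")) {
      stop("line ", i, ": expected 'positions:'")
    }
    pos <- as.numeric(strsplit(sub("^positions:\\s*", "", lines[i]),
                               "\\s+")[[1L]])
    if (length(pos) != S || anyNA(pos)) {
      stop("line ", i, ": positions line does not match segsites")
    }
    i <- i + 1L
    if (i + n_hap - 1L > length(lines)) {
      stop("line ", i, ": truncated haplotype block")
    }
    hap_lines <- lines[i:(i + n_hap - 1L)]
    if (any(nchar(hap_lines) != S) || any(grepl("[^01]", hap_lines))) {
      bad <- which(nchar(hap_lines) != S | grepl("[^01]", hap_lines))[1L]
      stop("line ", i + bad - 1L, ": malformed haplotype string")
    }
    mat <- matrix(
      as.integer(unlist(strsplit(hap_lines, "", fixed = TRUE))),
      nrow = n_hap, ncol = S, byrow = TRUE)
    recs[[length(recs) + 1L]] <- new_hap_matrix(mat, pos * L, n1, n2, k, L)
    i <- i + n_hap
  }
  if (length(recs) == 0L) stop("no ms records found in ", path)
  if (length(recs) == 1L) recs[[1L]] else recs
}
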