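#' @useDynLib virtualstroke, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor fft lm ks.test wilcox.test t.test pnorm qnorm rnorm
#'   runif sd var quantile median dgamma coef
#' @importFrom utils unzip modifyList
NULL

# Classed condition helper: every validation failure carries a distinct
# condition class ("vs_error_<code>") so callers and tests can discriminate.
vs_abort <- function(msg, code) {
  cond <- structure(
    class = c(paste0("vs_error_", code), "vs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

vs_warn <- function(msg, code) {
  warning(warningCondition(msg, class = c(paste0("vs_warning_", code), "vs_warning")))
}

is_square <- function(m) is.matrix(m) && nrow(m) == ncol(m)

#' Derive a child seed from a base seed and a counter
#'
#' All stochastic stages expand a single base seed into per-stage /
#' per-subject / per-grid-cell seeds with this documented counter scheme,
#' keeping every derived seed a valid 32-bit integer.
#'
#' @param seed base integer seed
#' @param counter nonnegative integer offset (stage, subject or cell index)
#' @return an integer seed in [0, 2^31 - 1]
#' @export
derive_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 1021L + as.numeric(counter)) %% 2147483647)
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# ---- minimal ZIP container ------------------------------------------------
# The image ships no `zip` binary, so archives are assembled by hand:
# entry payloads are raw deflate streams obtained by stripping the 2-byte
# zlib header and 4-byte Adler trailer from memCompress() output; the CRC32
# the ZIP directory requires is computed here (table-driven).  utils::unzip
# reads these archives back.

crc32_env <- new.env(parent = emptyenv())

crc32_table <- function() {
  if (is.null(crc32_env$tab)) {
    tab <- integer(256)
    for (i in 0:255) {
      cc <- i
      for (k in 1:8) {
        cc <- if (bitwAnd(cc, 1L) == 1L)
          bitwXor(-306674912L, bitwShiftR(cc, 1L))  # 0xEDB88320 reflected poly
        else bitwShiftR(cc, 1L)
      }
      tab[i + 1] <- cc
    }
    crc32_env$tab <- tab
  }
  crc32_env$tab
}

crc32_raw <- function(data) {
  tab <- crc32_table()
  crc <- -1L  # 0xFFFFFFFF
  bytes <- as.integer(data)
  for (b in bytes)
    crc <- bitwXor(bitwShiftR(crc, 8L), tab[bitwAnd(bitwXor(crc, b), 255L) + 1L])
  crc <- bitwXor(crc, -1L)
  (as.numeric(crc) + 2^32) %% 2^32  # unsigned value
}

le_bytes <- function(x, n) {
  out <- raw(n)
  for (i in seq_len(n)) {
    out[i] <- as.raw(x %% 256)
    x <- x %/% 256
  }
  out
}

zip_write <- function(path, entries) {
  con <- file(path, "wb")
  on.exit(close(con))
  offsets <- integer(length(entries))
  meta <- vector("list", length(entries))
  pos <- 0L
  for (i in seq_along(entries)) {
    name <- charToRaw(names(entries)[i])
    data <- entries[[i]]
    if (is.character(data)) data <- charToRaw(paste0(data, collapse = ""))
    gz <- memCompress(data, type = "gzip")  # zlib stream: 2-byte hdr, 4-byte adler
    deflated <- gz[3:(length(gz) - 4)]
    crc <- crc32_raw(data)
    local <- c(
      le_bytes(0x04034b50, 4), le_bytes(20, 2), le_bytes(0, 2),
      le_bytes(8, 2),                       # method: deflate
      le_bytes(0, 2), le_bytes(0x21, 2),    # dos time/date (fixed)
      le_bytes(crc, 4),
      le_bytes(length(deflated), 4), le_bytes(length(data), 4),
      le_bytes(length(name), 2), le_bytes(0, 2)
    )
    offsets[i] <- pos
    writeBin(c(local, name, deflated), con)
    pos <- pos + length(local) + length(name) + length(deflated)
    meta[[i]] <- list(name = name, crc = crc, csize = length(deflated),
                      usize = length(data))
  }
  cd_start <- pos
  cd_len <- 0L
  for (i in seq_along(entries)) {
    m <- meta[[i]]
    central <- c(
      le_bytes(0x02014b50, 4), le_bytes(20, 2), le_bytes(20, 2),
      le_bytes(0, 2), le_bytes(8, 2),
      le_bytes(0, 2), le_bytes(0x21, 2),
      le_bytes(m$crc, 4), le_bytes(m$csize, 4), le_bytes(m$usize, 4),
      le_bytes(length(m$name), 2), le_bytes(0, 2), le_bytes(0, 2),
      le_bytes(0, 2), le_bytes(0, 2), le_bytes(0, 4),
      le_bytes(offsets[i], 4)
    )
    writeBin(c(central, m$name), con)
    cd_len <- cd_len + length(central) + length(m$name)
  }
  eocd <- c(
    le_bytes(0x06054b50, 4), le_bytes(0, 2), le_bytes(0, 2),
    le_bytes(length(entries), 2), le_bytes(length(entries), 2),
    le_bytes(cd_len, 4), le_bytes(cd_start, 4), le_bytes(0, 2)
  )
  writeBin(eocd, con)
  invisible(path)
}

# Full-precision numeric matrix <-> text (round-trips doubles bitwise).
format_matrix_lines <- function(m) {
  apply(m, 1L, function(row) paste(sprintf("%.17g", row), collapse = " "))
}

parse_matrix_lines <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(strsplit(trimws(lines), "[[:space:]]+"), as.numeric)
  n <- unique(lengths(rows))
  if (length(n) != 1L)
    vs_abort("ragged matrix text: rows have differing lengths", "format")
  do.call(rbind, rows)
}
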