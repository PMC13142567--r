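#' @importFrom stats rbinom rnorm runif sd cor setNames
#' @importFrom utils head tail
#' @import data.table
NULL

VALID_CHROMS <- paste0("chr", c(1:22, "X", "Y"))

#' @noRd
assert_chromosome <- function(x, context = "chromosome") {
  bad <- setdiff(unique(x), VALID_CHROMS)
  if (length(bad)) {
    stop(sprintf("invalid %s label(s): %s (expected chr1..chr22, chrX, chrY)",
                 context, paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

# natural chromosome order: chr1..chr22, chrX, chrY
#' @noRd
chrom_sort <- function(chroms) {
  VALID_CHROMS[VALID_CHROMS %in% chroms]
}

# little-endian unsigned 64-bit written as two uint32 words (counts < 2^31
# in practice; high word is a plain carry)
#' @noRd
write_u64 <- function(con, x) {
  stopifnot(x >= 0, x < 2^53)
  lo <- x %% 2^32
  hi <- x %/% 2^32
  # writeBin() has no unsigned 32-bit type; fold into signed range bitwise
  as_i32 <- function(v) as.integer(if (v >= 2^31) v - 2^32 else v)
  writeBin(c(as_i32(lo), as_i32(hi)), con, size = 4L, endian = "little")
}

#' @noRd
read_u64 <- function(con) {
  w <- readBin(con, "integer", n = 2L, size = 4L, endian = "little")
  if (length(w) < 2L) stop("unexpected end of file while reading header", call. = FALSE)
  lo <- if (w[1] < 0) w[1] + 2^32 else w[1]
  hi <- if (w[2] < 0) w[2] + 2^32 else w[2]
  lo + hi * 2^32
}

# deterministic C-locale ordering for catalog keys
#' @noRd
order_c <- function(...) order(..., method = "radix")

#' @noRd
grom_log <- function(fmt, ..., verbose = TRUE) {
  if (isTRUE(verbose)) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), sprintf(fmt, ...))
  }
  invisible(NULL)
}

# run a block under a fixed seed without disturbing the caller's RNG stream
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
python_binary <- function() {
  py <- Sys.which(c("python3", "python"))
  py <- py[nzchar(py)]
  if (!length(py)) {
    stop("SQLite .db support requires a python3 interpreter on PATH ",
         "(standard library sqlite3)", call. = FALSE)
  }
  py[[1]]
}
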