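#' @keywords internal
"_PACKAGE"

## Shared small helpers. Nothing here is exported.

# round half away from zero, as chemical suppliers print molecular weights
# (base round() uses round-half-even, which would turn 224.255 into 224.25 or
# 224.26 depending on representation)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# deterministic 32-bit sub-seed: Lehmer step on (seed, salt); keeps every
# derived seed in [1, 2^31-2] so set.seed() always accepts it
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + salt * 7919) %% 2147483646 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

bn_log <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[bilayernet] ", ...)
  invisible(NULL)
}

stop_bn <- function(...) stop(..., call. = FALSE)

# pack a 0/1 integer vector into a hex string (4 bits per char, MSB first)
fp_to_hex <- function(bits) {
  stopifnot(length(bits) %% 4 == 0)
  nib <- matrix(as.integer(bits), nrow = 4)
  vals <- as.integer(c(8, 4, 2, 1) %*% nib)
  paste(c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
          "a", "b", "c", "d", "e", "f")[vals + 1L], collapse = "")
}

hex_to_fp <- function(hex) {
  chars <- strsplit(tolower(hex), "")[[1]]
  vals <- match(chars, c("0", "1", "2", "3", "4", "5", "6", "7", "8", "9",
                         "a", "b", "c", "d", "e", "f")) - 1L
  if (anyNA(vals)) stop_bn("invalid hex fingerprint string")
  as.integer(rbind(vals %/% 8, vals %/% 4 %% 2, vals %/% 2 %% 2, vals %% 2))
}
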