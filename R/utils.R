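#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed tables in pharmacology
#' conventionally round half up. A tiny relative fuzz guards against values
#' such as `2.675` that are stored just below the half-way point in binary.
#'
#' @param x numeric vector (non-negative values round half up, negative
#'   values half down, i.e. half away from zero).
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.675, 2) # 2.68, where round() gives 2.67
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# 32-bit FNV-1a over a vector of non-negative integers, done in doubles.
# Exact because every intermediate product is split below 2^53.
fnv1a <- function(ints) {
  h <- 2166136261
  for (v in ints) {
    # fold each of the 4 bytes of v (v < 2^32)
    v <- v %% 4294967296
    for (shift in c(1, 256, 65536, 16777216)) {
      byte <- floor(v / shift) %% 256
      h <- bitwXor(as.integer(h %% 2147483648) , as.integer(byte)) +
        (if (h >= 2147483648) 2147483648 else 0)
      # multiply by FNV prime 16777619 mod 2^32 without overflow
      lo <- h %% 65536
      hi <- floor(h / 65536)
      h <- ((hi * 16777619) %% 65536) * 65536 + lo * 16777619
      h <- h %% 4294967296
    }
  }
  h
}

# FNV-1a over the UTF-8 bytes of a string (used for config hashing)
fnv1a_string <- function(s) {
  fnv1a(as.integer(charToRaw(s)))
}

# coerce a gene-set argument (character vector, data frame with a node/gene
# column, or factor) to a unique character vector
as_gene_vector <- function(x, arg = "gene set") {
  if (is.data.frame(x)) {
    col <- intersect(c("gene", "node", "member"), names(x))[1]
    if (is.na(col)) {
      rlang::abort(
        paste0(arg, ": data frame input needs a 'gene' or 'node' column"),
        class = "signetpharm_value_error"
      )
    }
    x <- x[[col]]
  }
  unique(as.character(x))
}
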