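#' metacoloc: spatial colocalization of metabolite images and enzymes
#'
#' Integrates mass spectrometry imaging metabolite data with microscale
#' metaproteomics to score substrate-enzyme-product colocalization across
#' tissue microhabitats.
#'
#' @keywords internal
"_PACKAGE"

# Stable 32-bit string hash (polynomial rolling hash). Used to fan one global
# seed out to per-generator subseeds so adding a generator never perturbs the
# streams of the others.
str_hash <- function(x) {
  codes <- utf8ToInt(x)
  h <- 0
  for (c in codes) h <- (h * 31 + c) %% 2147483647
  h
}

#' Derive a per-generator subseed from a global seed
#'
#' Combines a global integer seed with a generator name by stable hashing, so
#' every generator draws from its own reproducible stream.
#'
#' @param seed integer global seed.
#' @param name character scalar naming the consumer.
#' @return An integer seed below 2^31.
#' @export
subseed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  as.integer((abs(seed) * 1000003 + str_hash(name)) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stop2 <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x >= 0 && x == floor(x)

# canonical ROI pair label
pair_label <- function(a, b) paste(a, b, sep = "/")

split_pair <- function(p) strsplit(p, "/", fixed = TRUE)

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}
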