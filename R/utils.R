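#' @import methods
#' @importFrom stats cor cor.test coef fisher.test lm median p.adjust pnorm
#'   prcomp pwilcox quantile rbinom rexp rgamma rlnorm rnbinom rnorm runif sd
#'   setNames var wilcox.test rmultinom
#' @importFrom utils head read.delim write.table packageVersion
NULL

# package-wide logging: plain messages so callers can suppressMessages()
.log <- function(...) message("[devostate] ", sprintf(...))

#' Derive a child seed from a master seed and a string key
#'
#' Splittable seeding: every randomized unit of work (a mega-cell replicate,
#' a permutation run for one gene set, one simulated cohort) draws its own
#' seed as a hash of a master seed and a descriptive key. Adding or removing
#' one unit therefore never perturbs the random draws of the others.
#'
#' @param seed integer master seed.
#' @param key character scalar identifying the unit of work.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @examples
#' splitSeed(17L, "liver:Hepatocyte:adult|rep3")
#' @export
splitSeed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key),
            length(key) == 1L)
  # FNV-1a style accumulation reduced mod (2^31 - 1); doubles are exact here
  h <- 84696351
  for (b in utf8ToInt(key)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer((h + as.numeric(seed)) %% 2147483647)
}

# evaluate expr under a local RNG state seeded with `seed`
.withSeed <- function(seed, expr) {
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

# canonical cell-state identifier
.stateId <- function(tissue, cell_type, stage) {
  paste(tissue, cell_type, stage, sep = ":")
}

# format numerics at 12 significant digits for deterministic TSV output
.fmtNum <- function(x) {
  out <- sprintf("%.12g", x)
  out[is.na(x)] <- "NA"
  out
}

# write a data.frame as canonical TSV ('.' decimal, UTF-8, no quotes)
.writeTsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) & !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], .fmtNum)
  tmp <- paste0(path, ".tmp")
  utils::write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  file.rename(tmp, path)
  invisible(path)
}
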