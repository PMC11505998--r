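#' @keywords internal
"_PACKAGE"

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# All generators and permutation routines funnel through this so that a given
# seed always produces the same output without clobbering the session RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

# Derive a per-stage child seed from a global seed by stable string hashing,
# so stages draw from decoupled streams. Kept below 2^31 - 1.
child_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 1000000007
  as.integer((as.numeric(seed) * 2654435761 + h) %% 2147483629)
}

# log-normal multiplicative noise with a given coefficient of variation,
# mean-one so expected signals are unbiased
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

#' Significance stars at conventional figure-legend levels
#'
#' @param p numeric vector of p-values.
#' @return character vector: `"***"` for p < 0.001, `"**"` for p < 0.01,
#'   `"*"` for p < 0.05, `"ns"` otherwise.
#' @export
significance_stars <- function(p) {
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[is.na(p)] <- NA_character_
  out
}

#' Write a tab-separated table
#'
#' UTF-8, tab-delimited, '.' decimal separator, header row, no quoting of
#' numerics. The common output format of every pipeline stage.
#'
#' @param x data frame.
#' @param path file path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tab-separated table with schema checking
#'
#' @param path file path.
#' @param required character vector of column names that must be present.
#' @return data frame.
#' @export
read_tsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(x))
    if (length(missing)) {
      stop("malformed table ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
    }
  }
  x
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line: ", substr(l, 1, 40))
    f[-(1:2)]
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  sets
}

# trapezoidal integral of y over x
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
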