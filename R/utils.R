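#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG state without disturbing the caller's
# stream. All stochastic operations in the package route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(expr)
}

# Derive a reproducible child seed from a master seed, staying within the
# 32-bit signed integer range.
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

clip_pir <- function(x) pmin(pmax(x, 0), 100)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_irtax <- function(msg, class) {
  stop(structure(class = c(class, "irtax_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Header comment written at the top of every table the package emits
#'
#' Writers prepend this line so outputs are self-describing and runs can be
#' traced back to a seed.
#' @param seed integer seed used to produce the table, or `NULL`.
#' @return a single `#`-prefixed character string.
#' @keywords internal
output_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("irtax"))
  if (is.null(seed)) sprintf("# irtax %s", v) else sprintf("# irtax %s seed=%d", v, as.integer(seed))
}

write_tsv_commented <- function(df, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(seed), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path, ...) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
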