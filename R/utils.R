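# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards so that seeded
#' generators behave as pure functions of their arguments.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) {
  stop(structure(
    class = c("vlpsizer_domain_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_domain("`", name, "` must be a single positive finite number")
  }
  invisible(x)
}

# Bilinear interpolation of matrix `img` (rows = y, cols = x) at 0-based
# pixel coordinates; pixel centers sit at integer coordinates.
bilinear_at <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(as.vector(x), 0), nc - 1)
  y <- pmin(pmax(as.vector(y), 0), nr - 1)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}
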