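#' Construct and validate a mixed-case interval-censored dataset
#'
#' A `mcic_data` object holds, for each subject, the shortest examination
#' interval `(u_left, u_right]` known to contain the event time, the
#' left-censoring indicator `delta1 = I(u_left = 0)`, the interval-censoring
#' indicator `delta2 = I(0 < u_left, u_right < Inf)`, and two covariate
#' blocks: `x` (latency) and `z` (incidence), which may share columns.
#' Right-censored subjects have `delta1 = delta2 = 0`, `u_left > 0` and
#' `u_right = Inf`; their cured status is unknown.
#'
#' If the `delta1`/`delta2` columns are absent they are derived from the
#' interval endpoints. Each row must describe exactly one of the three
#' censoring types:
#' \itemize{
#'   \item left-censored: `u_left = 0`, `u_right` finite, `delta1 = 1`;
#'   \item interval-censored: `0 < u_left < u_right < Inf`, `delta2 = 1`;
#'   \item right-censored: `u_left > 0`, `u_right = Inf`, `delta1 = delta2 = 0`.
#' }
#'
#' @param data a data frame with columns `u_left`, `u_right`, optionally
#'   `delta1` and `delta2`, plus covariate columns.
#' @param xvars character vector of latency covariate column names.
#' @param zvars character vector of incidence covariate column names.
#' @return an object of class `mcic_data`: a list with elements `u_left`,
#'   `u_right`, `delta1`, `delta2`, numeric matrices `x` and `z`, and the
#'   covariate names.
#' @examples
#' d <- data.frame(u_left = c(0, 0.5, 0.2), u_right = c(0.3, Inf, 0.6),
#'                 age = c(1.2, -0.3, 0.8), sex = c(1, 0, 1))
#' md <- mcic_data(d, xvars = c("age", "sex"), zvars = c("age", "sex"))
#' md
#' @export
mcic_data <- function(data, xvars, zvars) {
  stopifnot(is.data.frame(data))
  for (v in c("u_left", "u_right")) {
    if (!v %in% names(data)) stop("missing column '", v, "'")
  }
  uL <- as.numeric(data$u_left)
  uR <- as.numeric(data$u_right)
  if (anyNA(uL) || any(uL < 0)) stop("negative or missing u_left")
  uR[is.na(uR)] <- Inf  # empty right endpoint means right-censored
  if (any(uR[is.finite(uR)] < 0)) stop("negative u_right")

  if (all(c("delta1", "delta2") %in% names(data))) {
    d1 <- as.integer(data$delta1)
    d2 <- as.integer(data$delta2)
    if (!all(d1 %in% 0:1) || !all(d2 %in% 0:1)) {
      stop("delta1/delta2 must be 0 or 1")
    }
  } else {
    d1 <- as.integer(uL == 0)
    d2 <- as.integer(uL > 0 & is.finite(uR))
  }

  if (any(d1 + d2 > 1)) stop("delta1 + delta2 must be 0 or 1")
  if (any(d1 == 1 & uL > 0)) stop("left-censored rows require u_left = 0")
  if (any(d1 == 1 & !is.finite(uR))) {
    stop("left-censored rows require finite u_right")
  }
  bad <- is.finite(uR) & uL >= uR
  if (any(bad)) {
    stop("u_left >= u_right for row(s) ", paste(which(bad), collapse = ", "))
  }
  if (any(d2 == 1 & (uL <= 0 | !is.finite(uR)))) {
    stop("interval-censored rows require 0 < u_left < u_right < Inf")
  }
  rc <- d1 + d2 == 0
  if (any(rc & (uL <= 0 | is.finite(uR)))) {
    stop("right-censored rows require u_left > 0 and infinite u_right")
  }
  if (all(rc)) stop("dataset has no left- or interval-censored subject")

  miss <- setdiff(union(xvars, zvars), names(data))
  if (length(miss)) stop("missing covariate column(s): ",
                         paste(miss, collapse = ", "))
  x <- as.matrix(data[, xvars, drop = FALSE])
  z <- as.matrix(data[, zvars, drop = FALSE])
  storage.mode(x) <- "double"
  storage.mode(z) <- "double"
  if (anyNA(x) || anyNA(z)) stop("missing covariate values")

  structure(list(u_left = uL, u_right = uR, delta1 = d1, delta2 = d2,
                 x = x, z = z, x_names = xvars, z_names = zvars),
            class = "mcic_data")
}

#' @export
print.mcic_data <- function(x, ...) {
  n <- length(x$u_left)
  cat("Mixed-case interval-censored dataset:", n, "subjects\n")
  cat(sprintf("  left-censored %d, interval-censored %d, right-censored %d\n",
              sum(x$delta1), sum(x$delta2), sum(x$delta1 + x$delta2 == 0)))
  cat("  latency covariates x:", paste(x$x_names, collapse = ", "), "\n")
  cat("  incidence covariates z:", paste(x$z_names, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.mcic_data <- function(x, ...) {
  df <- data.frame(u_left = x$u_left, u_right = x$u_right,
                   delta1 = x$delta1, delta2 = x$delta2)
  xz <- cbind(x$x, x$z[, setdiff(x$z_names, x$x_names), drop = FALSE])
  cbind(df, as.data.frame(xz))
}

#' @export
length.mcic_data <- function(x) length(x$u_left)

#' Subset an mcic_data object by subject index
#' @param x an `mcic_data` object.
#' @param i integer or logical subject index (duplicates allowed, so the
#'   method also serves bootstrap resampling and oversampling).
#' @param ... unused.
#' @export
`[.mcic_data` <- function(x, i, ...) {
  structure(list(u_left = x$u_left[i], u_right = x$u_right[i],
                 delta1 = x$delta1[i], delta2 = x$delta2[i],
                 x = x$x[i, , drop = FALSE], z = x$z[i, , drop = FALSE],
                 x_names = x$x_names, z_names = x$z_names),
            class = "mcic_data")
}

#' Read a mixed-case interval-censored dataset from CSV
#'
#' The file layout is one row per subject with columns
#' `u_left,u_right,delta1,delta2,x_<name>...,z_<name>...`. The string
#' `"inf"` (any case) or an empty `u_right` field encodes an infinite right
#' endpoint. Covariate columns prefixed `x_` feed the latency, `z_` the
#' incidence; a column prefixed `xz_` is used in both blocks. The `delta`
#' columns may be omitted, in which case the censoring indicators are
#' derived from the endpoints.
#'
#' @param path CSV file path.
#' @return an [mcic_data] object.
#' @export
read_mcic <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if ("u_right" %in% names(df)) {
    ur <- df$u_right
    if (is.character(ur)) {
      ur <- trimws(ur)
      ur[ur == "" | tolower(ur) == "inf"] <- "Inf"
      ur <- as.numeric(ur)
    }
    df$u_right <- ur
  }
  xvars <- grep("^(x|xz)_", names(df), value = TRUE)
  zvars <- grep("^(z|xz)_", names(df), value = TRUE)
  if (!length(xvars) || !length(zvars)) {
    stop("no x_*/z_* covariate columns found in ", path)
  }
  mcic_data(df, xvars, zvars)
}

#' Write a mixed-case interval-censored dataset to CSV
#'
#' Inverse of [read_mcic]: infinite right endpoints are written as the
#' literal `"inf"` so that a write/read round trip reproduces the dataset.
#'
#' @param data an `mcic_data` object whose covariate names carry the
#'   `x_`/`z_`/`xz_` prefixes used by [read_mcic].
#' @param path output file path.
#' @export
write_mcic <- function(data, path) {
  stopifnot(inherits(data, "mcic_data"))
  df <- as.data.frame(data)
  df$u_right <- ifelse(is.finite(df$u_right), as.character(df$u_right), "inf")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
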