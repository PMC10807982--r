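# full-precision number formatting: %.17g round-trips doubles exactly
.fmt <- function(x) {
  ifelse(is.na(x), "", sprintf("%.17g", x))
}

#' Write a trajectory to CSV
#'
#' Writes header `t,n,i,e` and one row per output point at full double
#' precision (17 significant digits, `.` decimal separator, UNIX
#' newlines), so values round-trip losslessly through [read_trajectory()].
#'
#' @param traj A `culture_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "culture_trajectory"))
  lines <- c("t,n,i,e",
             paste(.fmt(traj$times), .fmt(traj$states[, "n"]),
                   .fmt(traj$states[, "i"]), .fmt(traj$states[, "e"]),
                   sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a trajectory CSV
#'
#' Reads a file written by [write_trajectory()], re-validating the simplex
#' invariant on every row.
#'
#' @param path File path.
#' @param params Optional [model_params()] to attach to the trajectory.
#' @return A `culture_trajectory` (with `params = NULL` unless supplied).
#' @export
read_trajectory <- function(path, params = NULL) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!identical(names(df), c("t", "n", "i", "e"))) {
    stop("expected columns t,n,i,e", call. = FALSE)
  }
  states <- as.matrix(df[, c("n", "i", "e")])
  apply(states, 1L, assert_simplex, slack = .simplex_slack)
  if (is.unsorted(df$t, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  new_trajectory(df$t, unname(states), params)
}

#' Write a sweep grid to long-format CSV
#'
#' One row per grid cell: the two axis coordinates (columns named after the
#' axes), `value`, and `reachable`. Unreachable or unconverged cells have
#' an empty `value` field and `reachable=false` -- never a sentinel number.
#' Numbers are written at full double precision as in
#' [write_trajectory()].
#'
#' @param grid A `sweep_grid`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(grid, path) {
  stopifnot(inherits(grid, "sweep_grid"))
  a1 <- rep(grid$axis1$values, times = length(grid$axis2$values))
  a2 <- rep(grid$axis2$values, each = length(grid$axis1$values))
  vals <- as.vector(grid$values)
  reach <- as.vector(grid$reachable)
  lines <- c(paste(grid$axis1$name, grid$axis2$name, "value", "reachable",
                   sep = ","),
             paste(.fmt(a1), .fmt(a2), .fmt(vals),
                   ifelse(reach, "true", "false"), sep = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Read a sweep grid CSV
#'
#' Reconstructs a `sweep_grid` from a file written by [write_sweep()].
#'
#' @param path File path.
#' @param quantity Label for the cell quantity (default `"value"`).
#' @param fixed Optional fixed-parameter list to attach.
#' @return A `sweep_grid`.
#' @export
read_sweep <- function(path, quantity = "value", fixed = list()) {
  df <- utils::read.csv(path)
  if (ncol(df) != 4L || !identical(names(df)[3:4], c("value", "reachable"))) {
    stop("expected columns <axis1>,<axis2>,value,reachable", call. = FALSE)
  }
  a1_name <- names(df)[1L]; a2_name <- names(df)[2L]
  a1 <- sort(unique(df[[1L]])); a2 <- sort(unique(df[[2L]]))
  values <- matrix(NA_real_, length(a1), length(a2))
  reachable <- matrix(NA, length(a1), length(a2))
  ra <- match(df[[1L]], a1); rb <- match(df[[2L]], a2)
  values[cbind(ra, rb)] <- as.numeric(df$value)
  reachable[cbind(ra, rb)] <- df$reachable == "true" | df$reachable == TRUE
  if (anyNA(reachable)) stop("incomplete grid", call. = FALSE)
  new_sweep_grid(a1_name, a1, a2_name, a2, values, reachable, fixed,
                 quantity)
}
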