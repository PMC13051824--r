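# Shell table for b-tensor encoded acquisitions.

#' Create a b-tensor encoding protocol (shell table)
#'
#' Describes the diffusion encoding of one session: one row per shell with
#' b-value, encoding shape, repetition count and (for linear encoding) a
#' direction.  Echo and repetition time are carried as metadata only.
#'
#' @param b Numeric vector of b-values, s/mm^2, nonnegative.  At most one
#'   b = 0 shell is permitted.
#' @param shape Character vector (recycled): `"spherical"` or `"linear"`.
#' @param repetitions Integer vector (recycled) of positive repeat counts.
#' @param directions Optional list of unit 3-vectors, required for linear
#'   shells (`NA` entries allowed for spherical shells).
#' @param echo_time Echo time, ms (metadata).
#' @param repetition_time Repetition time, ms (metadata).
#' @return A `btensor_protocol`: a data frame of shells with attributes
#'   `echo_time` and `repetition_time`.
#' @seealso [mdt_protocol()] for the two-shell high-b scheme this package
#'   is built around.
#' @export
btensor_protocol <- function(b, shape = "spherical", repetitions = 1L,
                             directions = NULL,
                             echo_time = NA_real_, repetition_time = NA_real_) {
  n <- length(b)
  shape <- rep_len(shape, n)
  repetitions <- rep_len(as.integer(repetitions), n)
  if (any(b < 0)) stop("b-values must be nonnegative")
  if (sum(b == 0) > 1L) stop("at most one b = 0 shell is permitted")
  if (any(repetitions < 1L)) stop("repetitions must be >= 1")
  if (!all(shape %in% c("spherical", "linear")))
    stop("shape must be 'spherical' or 'linear'")
  dirs <- vector("list", n)
  if (!is.null(directions)) dirs[seq_along(directions)] <- directions
  for (i in seq_len(n)) {
    if (shape[i] == "linear") {
      d <- dirs[[i]]
      if (is.null(d) || anyNA(d)) stop("linear shell ", i, " needs a direction")
      if (abs(sqrt(sum(d^2)) - 1) > 1e-9)
        stop("direction of shell ", i, " must have unit norm")
    }
  }
  shells <- data.frame(b = as.numeric(b), shape = shape,
                       repetitions = repetitions)
  shells$direction <- dirs
  structure(shells, class = c("btensor_protocol", "data.frame"),
            echo_time = echo_time, repetition_time = repetition_time)
}

#' The two-shell high-b spherical-encoding protocol for MDT
#'
#' The acquisition scheme the MDT estimator is designed for: spherical
#' tensor encoding at b = 0, 1500 and 2500 s/mm^2 with 1, 16 and 24
#' repetitions, echo time 110 ms, repetition time 2100 ms.
#'
#' @param repetitions Repetition counts for the three shells.
#' @return A `btensor_protocol`.
#' @export
mdt_protocol <- function(repetitions = c(1L, 16L, 24L)) {
  btensor_protocol(b = c(0, 1500, 2500), shape = "spherical",
                   repetitions = repetitions,
                   echo_time = 110, repetition_time = 2100)
}

#' @export
print.btensor_protocol <- function(x, ...) {
  cat(sprintf("<btensor_protocol> %d shell(s), TE %s ms, TR %s ms\n",
              nrow(x), format(attr(x, "echo_time")),
              format(attr(x, "repetition_time"))))
  print.data.frame(x[, c("b", "shape", "repetitions")], row.names = FALSE)
  invisible(x)
}

#' Write a protocol to a JSON sidecar
#'
#' Schema: `{"shells": [{"b": , "shape": , "dir": , "reps": }, ...],
#' "te_ms": , "tr_ms": }`.
#'
#' @param protocol A `btensor_protocol`.
#' @param path Output file path.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "btensor_protocol"))
  shells <- lapply(seq_len(nrow(protocol)), function(i) {
    s <- list(b = protocol$b[i], shape = protocol$shape[i],
              reps = protocol$repetitions[i])
    d <- protocol$direction[[i]]
    if (!is.null(d) && !anyNA(d)) s$dir <- as.numeric(d)
    s
  })
  jsonlite::write_json(
    list(shells = shells,
         te_ms = attr(protocol, "echo_time"),
         tr_ms = attr(protocol, "repetition_time")),
    path, auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read and validate a protocol JSON sidecar
#'
#' @param path Path to a JSON file written by [write_protocol()] (or
#'   conforming to its schema).
#' @return A `btensor_protocol`.
#' @export
read_protocol <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(j$shells) || !length(j$shells))
    stop("protocol JSON has no 'shells' array: ", path)
  b <- vapply(j$shells, function(s) as.numeric(s$b), numeric(1))
  shape <- vapply(j$shells, function(s) as.character(s$shape), character(1))
  reps <- vapply(j$shells, function(s) as.integer(s$reps), integer(1))
  dirs <- lapply(j$shells, function(s)
    if (is.null(s$dir)) NULL else as.numeric(unlist(s$dir)))
  te <- if (is.null(j$te_ms)) NA_real_ else as.numeric(j$te_ms)
  tr <- if (is.null(j$tr_ms)) NA_real_ else as.numeric(j$tr_ms)
  btensor_protocol(b, shape, reps, dirs, echo_time = te, repetition_time = tr)
}
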