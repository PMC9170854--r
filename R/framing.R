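#' Frame schedule for one reconstruction length
#'
#' Partitions the acquisition `[0, T)` into gap-free, disjoint half-open
#' intervals `[k*RL, (k+1)*RL)` of equal duration RL, for
#' `k = 0 .. floor(T/RL) - 1`. Remainder seconds at the end of the
#' acquisition are dropped, never pooled into a shorter final frame, so all
#' frames of a subset share the same reconstruction length and hence the
#' same count statistics.
#'
#' @param total_s total acquisition duration T (s).
#' @param rl_s reconstruction length RL (s), with `0 < RL <= T`.
#' @return an object of class `frame_schedule` with fields `rl_s`,
#'   `total_s` and `intervals` (a `floor(T/RL)` x 2 matrix of
#'   `[start, end)` times in seconds).
#' @export
make_schedule <- function(total_s, rl_s) {
  if (!is.numeric(rl_s) || rl_s <= 0) stop("rl_s must be > 0")
  if (rl_s > total_s) stop("rl_s must not exceed total_s")
  n <- floor(total_s / rl_s + 1e-9)
  starts <- (seq_len(n) - 1) * rl_s
  structure(list(rl_s = rl_s, total_s = total_s,
                 intervals = cbind(start_s = starts, end_s = starts + rl_s)),
            class = "frame_schedule")
}

#' @export
print.frame_schedule <- function(x, ...) {
  cat(sprintf("<frame_schedule> RL = %g s: %d frames covering [0, %g) of %g s\n",
              x$rl_s, nrow(x$intervals), nrow(x$intervals) * x$rl_s, x$total_s))
  invisible(x)
}

#' Default subset schedules
#'
#' The fourteen reconstruction lengths used to subdivide a 150 s
#' acquisition: 4, 6, 8, 10, 12, 15, 17, 19, 20, 22, 24, 26, 28 and 30 s.
#'
#' @param total_s total acquisition duration (default 150 s).
#' @param rl_list reconstruction lengths in seconds.
#' @return list of [make_schedule()] results, one per RL.
#' @export
default_schedules <- function(total_s = 150,
                              rl_list = c(4, 6, 8, 10, 12, 15, 17, 19, 20,
                                          22, 24, 26, 28, 30)) {
  lapply(rl_list, function(rl) make_schedule(total_s, rl))
}

#' Serialize / deserialize schedules as JSON
#'
#' @param schedules list of [make_schedule()] results.
#' @param path file to write to / read from.
#' @return `read_schedules_json` returns a list of `frame_schedule`s.
#' @export
write_schedules_json <- function(schedules, path) {
  payload <- lapply(schedules, function(s)
    list(T = s$total_s, RL = s$rl_s,
         intervals = unname(lapply(seq_len(nrow(s$intervals)),
                                   function(k) s$intervals[k, ]))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedules_json
#' @export
read_schedules_json <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(payload)), function(i)
    make_schedule(payload$T[i], payload$RL[i]))
}
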