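#' Write / read a trajectory table
#'
#' One row per snapshot: `time` (s) followed by the `nx * ny` voxel
#' concentrations in flattening order `k = i + nx j` (columns
#' `c0 ... c<n-1>`), tab-delimited.
#'
#' @param trajectory An `mnp_trajectory`.
#' @param path File path.
#' @return `write_trajectory` returns `path` invisibly; `read_trajectory`
#'   returns a list with `times` and `states` (states in columns).
#' @export
write_trajectory <- function(trajectory, path) {
  tab <- data.frame(time = trajectory$times, t(trajectory$states))
  names(tab) <- c("time", paste0("c", seq_len(nrow(trajectory$states)) - 1))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  list(times = tab$time,
       states = t(as.matrix(tab[, -1, drop = FALSE])))
}

#' Write / read a current schedule table
#'
#' One row per zero-order-hold segment: `t_start` (s) and one `coil_<i>`
#' column per coil (A), tab-delimited.
#'
#' @param schedule A [current_schedule()].
#' @param path File path.
#' @return `write_schedule` returns `path` invisibly; `read_schedule`
#'   returns the [current_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  seg_len <- schedule$t_f / schedule$n_t
  tab <- data.frame(t_start = (seq_len(schedule$n_t) - 1) * seg_len,
                    t(schedule$u))
  names(tab) <- c("t_start", paste0("coil_", seq_len(schedule$n_u)))
  attr(tab, "t_f") <- schedule$t_f
  utils::write.table(tab, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_schedule
#' @param t_f Horizon (s); by default inferred from the segment starts
#'   (uniform segments assumed).
#' @export
read_schedule <- function(path, t_f = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  n_t <- nrow(tab)
  if (is.null(t_f)) {
    seg_len <- if (n_t > 1) tab$t_start[2] - tab$t_start[1] else
      stop("cannot infer t_f from a single segment; pass `t_f`",
           call. = FALSE)
    t_f <- seg_len * n_t
  }
  current_schedule(t(as.matrix(tab[, -1, drop = FALSE])), t_f)
}

#' Write a POD basis for inspection
#'
#' Two tab-delimited tables: `<stem>_values.tsv` (mode index, singular
#' value, energy fraction, cumulative energy) and `<stem>_modes.tsv`
#' (the retained basis vectors, one column per mode).
#'
#' @param basis A [compute_pod()] result.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_pod <- function(basis, stem) {
  vals <- generics::tidy(basis)
  p1 <- paste0(stem, "_values.tsv")
  p2 <- paste0(stem, "_modes.tsv")
  utils::write.table(vals, p1, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  modes <- as.data.frame(basis$U)
  names(modes) <- paste0("mode_", seq_len(ncol(modes)))
  utils::write.table(modes, p2, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(c(p1, p2))
}
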