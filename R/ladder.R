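# Replica-exchange temperature ladders.
#
# Solute-tempering replica exchange emulates a ladder of effective
# temperatures by scaling the Hamiltonian of the hot replicas. The standard
# recipe spaces the rungs geometrically between the end temperatures so that
# neighbouring replicas overlap comparably along the whole ladder.

#' Geometric replica temperature ladder
#'
#' Rung `i` (1-based) of an `n`-rung ladder between `t_min` and `t_max` is
#' `t_min * (t_max / t_min)^((i - 1) / (n - 1))`: the ratio of successive
#' temperatures is constant. The canonical 20-replica ladder spanning
#' 300-800 K starts 300, 315.893, 332.629, ... K.
#'
#' @param t_min lowest (reference) temperature, K.
#' @param t_max highest temperature, K.
#' @param n number of replicas (>= 2; `n = 1` is allowed only for the
#'   degenerate `t_min == t_max` ladder).
#' @param t_ref reference temperature for the Hamiltonian scaling factors;
#'   defaults to `t_min`.
#' @return object of class `ladder_spec`: list with `t_min`, `t_max`,
#'   `n_replicas`, `temperatures` (full precision, K) and `scaling_factors`
#'   (`t_ref / T_i`, so 1 at the reference rung).
#' @examples
#' lad <- geometric_ladder(300, 800, 20)
#' round(lad$temperatures[2], 3)   # 315.893
#' @export
geometric_ladder <- function(t_min, t_max, n, t_ref = t_min) {
  check_pos(t_min, "t_min")
  check_pos(t_max, "t_max")
  if (t_min > t_max) stop_param("'t_min' must not exceed 't_max'")
  n <- check_count(n, "n", min = 1L)
  if (n == 1L && t_min != t_max)
    stop_param("n = 1 is only valid for a degenerate ladder (t_min == t_max)")
  temps <- if (n == 1L) t_min
           else t_min * (t_max / t_min)^((seq_len(n) - 1) / (n - 1))
  out <- structure(
    list(t_min = t_min, t_max = t_max, n_replicas = n,
         temperatures = temps, scaling_factors = t_ref / temps),
    class = "ladder_spec")
  out
}

#' @export
print.ladder_spec <- function(x, ...) {
  cat(sprintf("<ladder_spec> %d replicas, %.0f-%.0f K\n",
              x$n_replicas, x$t_min, x$t_max))
  cat("  T (K):     ", paste(format(round(x$temperatures, 3), trim = TRUE),
                             collapse = ", "), "\n")
  cat("  lambda:    ", paste(format(round(x$scaling_factors, 4), trim = TRUE),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Hamiltonian scaling factors for a temperature ladder
#'
#' Solute-tempering convention: the replica at effective temperature `T_i`
#' scales the tempered interactions by `lambda_i = t_ref / T_i`, so the
#' reference rung has `lambda = 1` and the product `lambda_i * T_i` is
#' constant. Published ladders often state only that scaling emulates
#' effective temperatures; this linear-in-inverse-temperature convention is
#' the standard one and is flagged here explicitly.
#'
#' @param ladder a `ladder_spec` from [geometric_ladder()].
#' @param t_ref reference temperature, K; defaults to the ladder's `t_min`.
#' @return numeric vector of scaling factors in (0, 1], decreasing.
#' @export
scaling_factors <- function(ladder, t_ref = ladder$t_min) {
  stopifnot(inherits(ladder, "ladder_spec"))
  check_pos(t_ref, "t_ref")
  t_ref / ladder$temperatures
}

#' Aggregate sampling time of a replica set
#'
#' Bookkeeping helper: `n_replicas` replicas of `per_replica_ns` each give an
#' effective aggregate of `n * per_replica_ns` nanoseconds (20 x 400 ns =
#' 8 microseconds).
#'
#' @param n_replicas replica count.
#' @param per_replica_ns per-replica simulated time, ns.
#' @return list with `total_ns` and `total_us`.
#' @export
aggregate_sampling <- function(n_replicas, per_replica_ns) {
  check_count(n_replicas, "n_replicas")
  check_pos(per_replica_ns, "per_replica_ns")
  total <- n_replicas * per_replica_ns
  list(total_ns = total, total_us = total / 1000)
}
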