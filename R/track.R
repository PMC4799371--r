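# squared-distance cost matrix between two detection sets, Inf beyond cap
sqdist_cost <- function(xa, ya, xb, yb, cap2) {
  d2 <- outer(xa, xb, "-")^2 + outer(ya, yb, "-")^2
  d2[d2 > cap2] <- Inf
  d2
}

# simulated-annealing solver for the same partial-matching objective as
# match_partial: minimize sum(matched cost) + unmatched * (#unmatched).
# Seeded, geometric cooling; kept for fidelity to annealing-based trackers
# and cross-checked against the assignment solver.
anneal_match <- function(cost, unmatched, seed, sweeps = 400) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0) return(integer(0))
  if (m == 0) return(rep(NA_integer_, n))
  energy <- function(mt) {
    matched <- !is.na(mt)
    sum(cost[cbind(which(matched), mt[matched])]) +
      unmatched * ((n - sum(matched)) + (m - sum(matched)))
  }
  with_seed(seed, {
    mt <- rep(NA_integer_, n)
    for (i in seq_len(n)) {       # greedy init
      best <- which.min(ifelse(seq_len(m) %in% mt, Inf, cost[i, ]))
      if (is.finite(cost[i, best]) && cost[i, best] < 2 * unmatched &&
          !(best %in% mt)) mt[i] <- best
    }
    e <- energy(mt)
    t0 <- max(unmatched, max(cost[is.finite(cost)], 0)) + 1
    n_iter <- sweeps * max(n, m)
    temp <- t0
    alpha <- exp(log(1e-4 / t0) / n_iter)
    for (it in seq_len(n_iter)) {
      cand <- mt
      i <- sample.int(n, 1)
      j <- sample.int(m + 1, 1) - 1L          # 0 = unassign
      if (j == 0L) {
        cand[i] <- NA_integer_
      } else {
        holder <- which(mt == j)
        if (length(holder)) cand[holder] <- cand[i]
        cand[i] <- j
      }
      ok <- is.na(cand[i]) || is.finite(cost[i, cand[i]])
      h <- which(cand != 0)
      if (ok) {
        e2 <- energy(cand)
        if (e2 <= e || runif(1) < exp((e - e2) / temp)) {
          mt <- cand; e <- e2
        }
      }
      temp <- temp * alpha
    }
    # greedy descent polish
    repeat {
      improved <- FALSE
      for (i in seq_len(n)) {
        for (j in c(NA_integer_, seq_len(m))) {
          cand <- mt
          if (!is.na(j)) {
            if (!is.finite(cost[i, j])) next
            holder <- which(mt == j)
            if (length(holder)) cand[holder] <- cand[i]
          }
          cand[i] <- j
          e2 <- energy(cand)
          if (e2 < e - 1e-12) { mt <- cand; e <- e2; improved <- TRUE }
        }
      }
      if (!improved) break
    }
    mt
  })
}

#' Link localizations into trajectories
#'
#' Frame-to-frame linking: for each pair of consecutive frames, a globally
#' optimal one-to-one assignment minimizes the total squared displacement
#' over candidate pairs closer than `d_max`, with a fixed cost `d_max^2` per
#' unmatched detection (birth/death). Gap closing then joins trajectory
#' ends to trajectory starts up to `max_gap` skipped frames later, within a
#' distance cap `d_max * sqrt(gap)`, shortest gaps first, using the same
#' assignment machinery. Trajectories with fewer than 2 points are
#' discarded (their detections stay unlinked singletons).
#'
#' @param table a [loc_table()], single channel.
#' @param d_max maximum per-frame displacement (um); default matches a
#'   fastest expected diffusion of 5 um^2/s at the table's frame interval.
#' @param max_gap maximum number of frames a molecule may blink off.
#' @param solver "assignment" (deterministic Hungarian, default) or
#'   "simulated_annealing" (seeded; same objective).
#' @param seed seed for the annealing solver.
#' @return data frame of class `traj_table` (`traj_id, frame, x, y`, plus
#'   carried-through columns); attributes `d_max`, `max_gap_used`,
#'   `n_singletons`, `frame_interval`.
#' @export
link_detections <- function(table, d_max = NULL, max_gap = 2,
                            solver = c("assignment", "simulated_annealing"),
                            seed = 1) {
  solver <- match.arg(solver)
  if (length(unique(table$channel)) > 1) {
    stop("link_detections expects a single channel")
  }
  dt <- attr(table, "frame_interval") %||% 0.02
  if (is.null(d_max)) d_max <- sqrt(4 * 5 * dt)
  stopifnot(d_max > 0, max_gap >= 0)
  empty <- {
    e <- data.frame(traj_id = integer(0), frame = integer(0),
                    x = numeric(0), y = numeric(0))
    class(e) <- c("traj_table", "data.frame")
    e
  }
  if (nrow(table) == 0) return(empty)
  tab <- as.data.frame(table)[order(table$frame), ]
  n <- nrow(tab)
  traj <- integer(n)
  next_id <- 1L
  by_frame <- split(seq_len(n), tab$frame)
  frames <- as.integer(names(by_frame))
  solve_pair <- function(cost, cap2, tag) {
    if (solver == "assignment") match_partial(cost, cap2)
    else anneal_match(cost, cap2, stage_seed(seed, tag))
  }
  prev <- NULL
  for (k in seq_along(frames)) {
    cur <- by_frame[[k]]
    if (!is.null(prev) && frames[k] - frames[k - 1] == 1L) {
      cost <- sqdist_cost(tab$x[prev], tab$y[prev],
                          tab$x[cur], tab$y[cur], d_max^2)
      m <- solve_pair(cost, d_max^2, paste0("link", frames[k]))
      for (i in seq_along(prev)) {
        if (!is.na(m[i])) traj[cur[m[i]]] <- traj[prev[i]]
      }
    }
    for (j in cur) {
      if (traj[j] == 0L) { traj[j] <- next_id; next_id <- next_id + 1L }
    }
    prev <- cur
  }
  # gap closing, shortest gaps first
  if (max_gap > 0) {
    for (df in 2:(max_gap + 1L)) {
      sp <- split(seq_len(n), traj)
      ends <- vapply(sp, function(ii) ii[which.max(tab$frame[ii])], 0L)
      starts <- vapply(sp, function(ii) ii[which.min(tab$frame[ii])], 0L)
      cap <- d_max * sqrt(df)
      e_ok <- ends
      s_ok <- starts
      pairs_possible <- outer(tab$frame[s_ok], tab$frame[e_ok],
                              function(s, e) s - e == df)
      if (!any(pairs_possible)) next
      cost <- sqdist_cost(tab$x[e_ok], tab$y[e_ok],
                          tab$x[s_ok], tab$y[s_ok], cap^2)
      cost[!t(pairs_possible)] <- Inf
      if (!any(is.finite(cost))) next
      m <- solve_pair(cost, cap^2, paste0("gap", df))
      for (i in seq_along(e_ok)) {
        if (!is.na(m[i])) {
          from <- traj[s_ok[m[i]]]
          to <- traj[e_ok[i]]
          if (from != to) traj[traj == from] <- to
        }
      }
    }
  }
  len <- table(traj)
  keep <- traj %in% as.integer(names(len)[len >= 2])
  n_singletons <- sum(!keep)
  out <- tab[keep, , drop = FALSE]
  out$traj_id <- as.integer(factor(traj[keep],
                                   levels = unique(traj[keep])))
  out <- out[order(out$traj_id, out$frame),
             c("traj_id", setdiff(names(out), "traj_id"))]
  rownames(out) <- NULL
  class(out) <- c("traj_table", "data.frame")
  attr(out, "d_max") <- d_max
  attr(out, "max_gap_used") <- max_gap
  attr(out, "n_singletons") <- n_singletons
  attr(out, "frame_interval") <- dt
  out
}

#' Summary counts for a trajectory set
#'
#' Reports the number of trajectories normalized per 10 um of dendrite, the
#' mean number of detections per frame, and (optionally) trajectory counts
#' pooled over fixed-length time intervals.
#'
#' @param traj a `traj_table` (long format).
#' @param dendrite_length dendritic segment length (um), > 0.
#' @param interval_frames optional pooling interval (frames); a trajectory
#'   is assigned to the interval containing its first frame.
#' @return list: `n_trajectories`, `traj_per_10um`, `detections_per_frame`,
#'   and `interval_counts` (data frame) when `interval_frames` is given.
#' @export
trajectory_summary <- function(traj, dendrite_length, interval_frames = NULL) {
  stopifnot(dendrite_length > 0)
  ids <- unique(traj$traj_id)
  n_traj <- length(ids)
  n_frames <- if (nrow(traj) == 0) 1L else diff(range(traj$frame)) + 1L
  out <- list(
    n_trajectories = n_traj,
    traj_per_10um = n_traj / (dendrite_length / 10),
    detections_per_frame = nrow(traj) / n_frames)
  if (!is.null(interval_frames)) {
    first <- tapply(traj$frame, traj$traj_id, min)
    iv <- floor(first / interval_frames)
    tabcnt <- table(iv)
    out$interval_counts <- data.frame(
      interval = as.integer(names(tabcnt)),
      n_trajectories = as.integer(tabcnt))
  }
  out
}
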