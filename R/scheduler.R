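#' Worker/memory-node topology
#'
#' Describes how workers map onto memory nodes and the inter-node access
#' cost, mirroring the layout of a cc-NUMA shared-memory machine (real
#' machines can export theirs; tests use synthetic matrices).
#'
#' @param node_of integer vector: memory-node id (1-based) per worker.
#' @param distance symmetric non-negative node x node cost matrix with the
#'   diagonal minimal in each row.
#' @return a `numa_topology`.
#' @export
numa_topology <- function(node_of, distance) {
  node_of <- as.integer(node_of)
  distance <- as.matrix(distance)
  if (!isTRUE(all.equal(distance, t(distance))))
    stop("distance matrix must be symmetric")
  if (any(distance < 0)) stop("distances must be non-negative")
  if (any(diag(distance) > apply(distance, 1L, min)))
    stop("diagonal must be minimal in each row")
  if (max(node_of) > nrow(distance)) stop("node id exceeds distance matrix")
  structure(list(n_workers = length(node_of), node_of = node_of,
                 distance = distance),
            class = "numa_topology")
}

#' Scheduler state over a bucket partition
#'
#' @param partition a `bucket_partition`.
#' @param n_workers worker count.
#' @return a `scheduler_state`: per-worker FIFO bucket queues, the ordered
#'   idle list, and an empty donation log.
#' @export
scheduler_state <- function(partition, n_workers) {
  queues <- vector("list", n_workers)
  for (w in seq_len(n_workers)) queues[[w]] <- integer()
  for (bk in seq_along(partition$buckets)) {
    w <- partition$owner[bk]
    queues[[w]] <- c(queues[[w]], bk)
  }
  idle <- which(vapply(queues, length, 1L) == 0L)
  structure(list(queues = queues, idle = as.integer(idle),
                 donations = data.frame(donor = integer(), recipient = integer(),
                                        n_buckets = integer(), step = integer())),
            class = "scheduler_state")
}

#' Choose a donation recipient from the idle list
#'
#' `original` policy: the first worker in the idle list. `hierarchical`
#' policy: the idle worker whose memory node is at the shortest distance
#' from the donor's node; ties keep the earliest entry in the idle list,
#' so on uniform-distance topologies the two policies coincide.
#'
#' @param donor busy worker id.
#' @param state a `scheduler_state`.
#' @param topology a `numa_topology`.
#' @param policy "original" or "hierarchical".
#' @return recipient worker id, or NA integer if the idle list is empty.
#' @export
choose_recipient <- function(donor, state, topology,
                             policy = c("hierarchical", "original")) {
  policy <- match.arg(policy)
  idle <- state$idle
  if (!length(idle)) return(NA_integer_)
  if (policy == "original") return(idle[1L])
  dn <- topology$node_of[donor]
  d <- topology$distance[dn, topology$node_of[idle]]
  idle[which.min(d)] # which.min keeps the first minimum in list order
}

#' Donate a fraction of the donor's buckets
#'
#' Transfers `ceiling(fraction * queue length)` buckets from the tail of
#' the donor's queue; a donor holding at most one bucket never donates.
#' The recipient leaves the idle list and the donation is logged.
#'
#' @param donor,recipient worker ids (recipient must be idle).
#' @param state a `scheduler_state`.
#' @param fraction fraction of the donor queue to transfer (default 0.5).
#' @param step event counter recorded in the log.
#' @return the updated `scheduler_state`.
#' @export
donate <- function(donor, recipient, state, fraction = 0.5, step = 0L) {
  nq <- length(state$queues[[donor]])
  if (nq <= 1L) return(state)
  if (!(recipient %in% state$idle)) stop("recipient is not idle")
  k <- as.integer(ceiling(fraction * nq))
  take <- state$queues[[donor]][(nq - k + 1L):nq]
  state$queues[[donor]] <- state$queues[[donor]][seq_len(nq - k)]
  state$queues[[recipient]] <- c(state$queues[[recipient]], take)
  state$idle <- state$idle[state$idle != recipient]
  state$donations <- rbind(state$donations,
                           data.frame(donor = donor, recipient = recipient,
                                      n_buckets = k, step = as.integer(step)))
  state
}

#' Speculative all-or-nothing cavity locking
#'
#' Acquires locks on an element set in canonical (sorted id) order; if any
#' element is already held by another owner, all partial acquisitions are
#' released (the caller should set its `lock_failed` flag and move on).
#'
#' @param elements integer element ids (non-empty).
#' @param table a lock table from [lock_table()].
#' @param owner integer owner id.
#' @return TRUE if the whole cavity was acquired, FALSE otherwise.
#' @export
try_lock_cavity <- function(elements, table, owner = 1L) {
  elements <- sort(unique(as.integer(elements)))
  if (!length(elements)) stop("empty element set")
  got <- integer()
  for (e in elements) {
    key <- as.character(e)
    holder <- table$locks[[key]]
    if (!is.null(holder) && holder != owner) {
      for (g in got) rm(list = as.character(g), envir = table$locks)
      return(FALSE)
    }
    if (is.null(holder)) {
      assign(key, owner, envir = table$locks)
      got <- c(got, e)
    }
  }
  TRUE
}

#' Create an empty lock table
#' @return a `lock_table` (environment-backed).
#' @export
lock_table <- function() {
  structure(list(locks = new.env(parent = emptyenv())), class = "lock_table")
}

#' Release all locks held by an owner
#' @param table a lock table.
#' @param owner owner id.
#' @export
release_locks <- function(table, owner) {
  for (key in ls(table$locks)) {
    if (identical(table$locks[[key]], owner)) rm(list = key, envir = table$locks)
  }
  invisible(table)
}

#' Deterministic load-balancing simulation
#'
#' Event-driven simulation of bucket processing: each worker consumes its
#' FIFO queue; on finishing a bucket, a still-busy worker donates half its
#' remaining queue to the recipient chosen by `policy` (if anyone is
#' idle); a worker with an empty queue joins the idle list. Reports the
#' donation log, the total donation distance (the remote-transfer cost
#' proxy) and the makespan.
#'
#' @param topology a `numa_topology`.
#' @param costs numeric vector of per-bucket processing costs.
#' @param policy "original" or "hierarchical".
#' @param fraction donation fraction (default 0.5).
#' @param owner initial bucket owner per bucket (default round-robin).
#' @param seed recorded in the output (the simulation itself is
#'   deterministic).
#' @return list `donations`, `total_distance`, `makespan`, `policy`.
#' @export
simulate_load_balance <- function(topology, costs, policy = c("hierarchical", "original"),
                                  fraction = 0.5, owner = NULL, seed = 1L) {
  policy <- match.arg(policy)
  nw <- topology$n_workers
  nb <- length(costs)
  if (is.null(owner)) owner <- ((seq_len(nb) - 1L) %% nw) + 1L
  queues <- lapply(seq_len(nw), function(w) which(owner == w))
  tnow <- numeric(nw)          # per-worker clock
  busy_until <- rep(NA_real_, nw)
  current <- rep(NA_integer_, nw)
  idle <- integer()
  donations <- list()
  step <- 0L
  start_next <- function(w) {
    if (length(queues[[w]])) {
      current[w] <<- queues[[w]][1L]
      queues[[w]] <<- queues[[w]][-1L]
      busy_until[w] <<- tnow[w] + costs[current[w]]
    } else {
      current[w] <<- NA_integer_
      busy_until[w] <<- NA_real_
      if (!(w %in% idle)) idle <<- c(idle, w)
    }
  }
  for (w in seq_len(nw)) start_next(w)
  repeat {
    active <- which(!is.na(busy_until))
    if (!length(active)) break
    w <- active[order(busy_until[active], active)][1L]
    tnow[w] <- busy_until[w]
    step <- step + 1L
    # bucket finished; donate before continuing if someone is idle
    if (length(queues[[w]]) > 1L && length(idle)) {
      st <- structure(list(queues = queues, idle = idle), class = "scheduler_state")
      rec <- choose_recipient(w, st, topology, policy)
      if (!is.na(rec)) {
        nq <- length(queues[[w]])
        k <- as.integer(ceiling(fraction * nq))
        take <- queues[[w]][(nq - k + 1L):nq]
        queues[[w]] <- queues[[w]][seq_len(nq - k)]
        queues[[rec]] <- c(queues[[rec]], take)
        idle <- idle[idle != rec]
        tnow[rec] <- max(tnow[rec], tnow[w])
        donations[[length(donations) + 1L]] <- data.frame(
          donor = w, recipient = rec, n_buckets = k, step = step,
          distance = topology$distance[topology$node_of[w], topology$node_of[rec]])
        start_next(rec)
      }
    }
    start_next(w)
  }
  don <- if (length(donations)) do.call(rbind, donations)
         else data.frame(donor = integer(), recipient = integer(),
                         n_buckets = integer(), step = integer(),
                         distance = numeric())
  list(donations = don, total_distance = sum(don$distance),
       makespan = max(tnow), policy = policy, seed = as.integer(seed))
}
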