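mk_topo <- function(node_of, D) numa_topology(node_of, D)

test_that("recipient choice: shortest-distance argmin with first-idle ties", {
  D <- matrix(c(0, 12, 32,
                12, 0, 20,
                32, 20, 0), 3L, 3L, byrow = TRUE)
  topo <- mk_topo(c(1L, 2L, 3L, 1L), D)
  st <- structure(list(queues = list(integer(), 1:3, integer(), integer()),
                       idle = c(1L, 3L)),
                  class = "scheduler_state")
  # donor 2 (node 2): d(2,1)=12 for worker1, d(2,3)=20 for worker3
  expect_equal(choose_recipient(2L, st, topo, "hierarchical"), 1L)
  expect_equal(choose_recipient(2L, st, topo, "original"), 1L)
  # empty idle list
  st0 <- st; st0$idle <- integer()
  expect_true(is.na(choose_recipient(2L, st0, topo, "hierarchical")))
  # uniform distances: hierarchical reproduces first-idle
  Du <- matrix(5, 3L, 3L); diag(Du) <- 0
  topo_u <- mk_topo(c(1L, 2L, 3L, 1L), Du)
  st2 <- st; st2$idle <- c(3L, 1L) # idle order deliberately not sorted
  expect_equal(choose_recipient(2L, st2, topo_u, "hierarchical"),
               choose_recipient(2L, st2, topo_u, "original"))
})

test_that("hierarchical choice equals brute-force argmin on random topologies", {
  set.seed(99)
  for (i in 1:1000) {
    nn <- sample(2:5, 1L)
    nw <- sample(2:8, 1L)
    D <- matrix(runif(nn * nn, 1, 100), nn, nn)
    D <- (D + t(D)) / 2
    diag(D) <- 0
    node_of <- sample(nn, nw, replace = TRUE)
    topo <- mk_topo(node_of, D)
    donor <- sample(nw, 1L)
    idle <- sample(setdiff(seq_len(nw), donor),
                   sample(seq_len(nw - 1L), 1L))
    st <- structure(list(queues = vector("list", nw), idle = idle),
                    class = "scheduler_state")
    got <- choose_recipient(donor, st, topo, "hierarchical")
    d <- D[node_of[donor], node_of[idle]]
    expect_equal(got, idle[which.min(d)]) # oracle: scan idle list in order
  }
})

test_that("donation moves ceil(fraction * queue) tail buckets", {
  topo <- mk_topo(c(1L, 1L), matrix(0, 1L, 1L))
  st <- structure(list(queues = list(1:8, integer()), idle = 2L,
                       donations = data.frame(donor = integer(),
                                              recipient = integer(),
                                              n_buckets = integer(),
                                              step = integer())),
                  class = "scheduler_state")
  st2 <- donate(1L, 2L, st, fraction = 0.5)
  expect_equal(st2$queues[[1L]], 1:4)
  expect_equal(st2$queues[[2L]], 5:8)
  expect_length(st2$idle, 0L)
  expect_equal(st2$donations$n_buckets, 4L)
  # single-bucket donor: no-op
  st1 <- st; st1$queues[[1L]] <- 5L
  expect_identical(donate(1L, 2L, st1, 0.5)$queues, st1$queues)
})

test_that("donation sequences preserve the scheduler invariants", {
  set.seed(12)
  nw <- 4L
  topo <- mk_topo(rep(1:2, each = 2L), matrix(c(0, 7, 7, 0), 2L))
  all_buckets <- 1:40
  st <- structure(list(
    queues = split(all_buckets, rep(1:2, each = 20L))[c("1", "2")],
    idle = c(3L, 4L),
    donations = data.frame(donor = integer(), recipient = integer(),
                           n_buckets = integer(), step = integer())),
    class = "scheduler_state")
  st$queues <- c(st$queues, list(integer(), integer()))
  for (i in 1:10) {
    busy <- which(vapply(st$queues, length, 1L) > 1L)
    if (!length(busy) || !length(st$idle)) break
    donor <- sample(busy, 1L)
    rec <- choose_recipient(donor, st, topo, "hierarchical")
    st <- donate(donor, rec, st, fraction = runif(1, 0.2, 0.8), step = i)
    # every bucket owned exactly once
    owned <- sort(unname(unlist(st$queues)))
    expect_equal(owned, all_buckets)
    # idle iff queue empty, for workers that have ever held work
    for (w in st$idle) expect_length(st$queues[[w]], 0L)
  }
})

test_that("cavity locking is all-or-nothing with full rollback", {
  tab <- lock_table()
  expect_true(try_lock_cavity(c(3L, 1L, 2L), tab, owner = 1L))
  # disjoint cavity: acquires
  expect_true(try_lock_cavity(c(10L, 11L), tab, owner = 2L))
  # overlapping cavity: fails and rolls back
  before <- sort(ls(tab$locks))
  expect_false(try_lock_cavity(c(2L, 20L), tab, owner = 3L))
  expect_identical(sort(ls(tab$locks)), before) # rollback left no trace
  release_locks(tab, 1L)
  expect_true(try_lock_cavity(c(2L, 20L), tab, owner = 3L))
  expect_error(try_lock_cavity(integer(), tab, 1L), "empty")
})

test_that("simulation: hierarchical cuts mean donation distance on skewed loads", {
  set.seed(7)
  # two memory nodes, far apart; workers 1-2 on node 1, workers 3-4 on 2.
  # the greedy choice is an average-case advantage (an early near-node
  # donation can force a later far one), so the claim is about the mean
  topo <- mk_topo(c(1L, 1L, 2L, 2L), matrix(c(0, 40, 40, 0), 2L))
  ratios <- vapply(1:20, function(rep) {
    costs <- c(runif(30, 5, 10), runif(10, 0.1, 0.5)) # skewed load
    owner <- rep(c(1L, 3L), each = 20L)
    sh <- simulate_load_balance(topo, costs, "hierarchical", owner = owner)
    so <- simulate_load_balance(topo, costs, "original", owner = owner)
    if (so$total_distance == 0) 1 else sh$total_distance / so$total_distance
  }, numeric(1))
  expect_lt(mean(ratios), 1)
  # single worker: no donations
  t1 <- mk_topo(1L, matrix(0, 1L, 1L))
  s1 <- simulate_load_balance(t1, runif(10), "hierarchical")
  expect_equal(nrow(s1$donations), 0L)
  # determinism
  sA <- simulate_load_balance(topo, 1:12, "hierarchical")
  sB <- simulate_load_balance(topo, 1:12, "hierarchical")
  expect_identical(sA$donations, sB$donations)
  expect_identical(sA$makespan, sB$makespan)
})

test_that("uniform-distance topologies give identical donation logs", {
  Du <- matrix(3, 2L, 2L); diag(Du) <- 0
  topo <- mk_topo(c(1L, 1L, 2L, 2L), Du)
  set.seed(3)
  costs <- runif(24, 0.5, 4)
  sh <- simulate_load_balance(topo, costs, "hierarchical")
  so <- simulate_load_balance(topo, costs, "original")
  expect_identical(sh$donations[c("donor", "recipient", "n_buckets", "step")],
                   so$donations[c("donor", "recipient", "n_buckets", "step")])
})

test_that("topology validation rejects malformed distance matrices", {
  expect_error(numa_topology(1:2, matrix(c(0, 1, 2, 0), 2L)), "symmetric")
  expect_error(numa_topology(1:2, matrix(c(0, -1, -1, 0), 2L)),
               "non-negative")
  expect_error(numa_topology(c(1L, 3L), matrix(0, 2L, 2L)), "exceeds")
})
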