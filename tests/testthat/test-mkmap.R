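two_state_q <- function(q12, q21 = q12) {
  Q <- matrix(c(-q12, q12, q21, -q21), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  Q
}

test_that("Mk likelihood matches closed forms", {
  # two tips joined by a total path of length 1, symmetric q = 0.5,
  # identical states, uniform root: likelihood = pi_a * P_aa(1) with
  # P_aa(1) = (1 + exp(-2 q t)) / 2 = 0.68394
  tr <- read_newick("(A:0.5,B:0.5);")
  Q <- two_state_q(0.5)
  ll <- mk_loglik(tr, c(A = "a", B = "a"), Q, "uniform")
  expect_equal(exp(ll), 0.5 * 0.5 * (1 + exp(-1)), tolerance = 1e-9)
  expect_equal(0.5 * (1 + exp(-1)), 0.68394, tolerance = 1e-6)

  # vanishing rates with identical tip states: logL -> log(root prior)
  lls <- mk_loglik(tr, c(A = "a", B = "a"), two_state_q(1e-9), "uniform")
  expect_equal(lls, log(0.5), tolerance = 1e-6)

  # "?" contributes a flat likelihood vector
  llq <- mk_loglik(tr, c(A = "a", B = "?"), Q, "uniform")
  expect_equal(exp(llq), 0.5, tolerance = 1e-9)
})

test_that("pruning equals exhaustive enumeration on all small shapes", {
  shapes <- c("(A:0.7,B:1.3);",
              "((A:1,B:1):0.5,C:1.5);",
              "((A:1,B:1):1,(C:0.5,D:0.5):1.5);",
              "(((A:1,B:1):1,C:2):0.5,D:2.5);")
  states2 <- c("a", "b")
  qgrid <- c(0.1, 0.5, 2)
  for (s in shapes) {
    tr <- read_newick(s)
    n <- ape::Ntip(tr)
    for (q12 in qgrid) for (q21 in qgrid) {
      Q <- two_state_q(q12, q21)
      pi0 <- setNames(c(0.5, 0.5), states2)
      set.seed(n * 100 + q12 * 10 + q21)
      ts <- setNames(sample(states2, n, replace = TRUE), tr$tip.label)
      expect_equal(mk_loglik(tr, ts, Q, pi0),
                   enum_mk_loglik(tr, ts, Q, pi0), tolerance = 1e-10)
    }
  }
  # three states on the 3-tip shape
  tr <- read_newick("((A:1,B:1):0.5,C:1.5);")
  Q3 <- matrix(0.4, 3, 3, dimnames = list(c("a", "b", "c"),
                                          c("a", "b", "c")))
  diag(Q3) <- -0.8
  pi3 <- setNames(rep(1 / 3, 3), c("a", "b", "c"))
  ts <- c(A = "a", B = "c", C = "b")
  expect_equal(mk_loglik(tr, ts, Q3, pi3),
               enum_mk_loglik(tr, ts, Q3, pi3), tolerance = 1e-10)
})

test_that("Mk fitting is label-symmetric, nested, and recovers rates", {
  tr <- rand_tree(80, 17)
  Q <- two_state_q(1.5, 0.7)
  # simulate tip states by drawing a stochastic map from the prior:
  # forward simulation along the tree
  sim_tips <- function(tree, Q, seed) {
    set.seed(seed)
    states <- rownames(Q)
    n_tip <- ape::Ntip(tree)
    st <- integer(n_tip + tree$Nnode)
    st[n_tip + 1] <- sample(length(states), 1)
    pre <- rev(seq_len(nrow(tree$edge)))
    post <- reorder(tree, "postorder")
    for (e in pre) {
      P <- ape::matexpo(Q * post$edge.length[e])
      st[post$edge[e, 2]] <- sample(length(states), 1,
                                    prob = P[st[post$edge[e, 1]], ])
    }
    setNames(states[st[seq_len(n_tip)]], tree$tip.label)
  }
  ts <- sim_tips(tr, Q, 3)
  fit <- fit_mk(tr, ts, model = "ARD")

  # relabelling permutes Q consistently
  swap <- c(a = "b", b = "a")
  fit2 <- fit_mk(tr, setNames(unname(swap[ts]), names(ts)), model = "ARD")
  expect_equal(fit$Q["a", "b"], fit2$Q["b", "a"], tolerance = 1e-4)
  expect_equal(fit$logL, fit2$logL, tolerance = 1e-6)

  # ARD nests SYM
  expect_gte(fit$logL, fit_mk(tr, ts, model = "SYM")$logL - 1e-6)

  # rate recovery within a factor of 3 (median over replicates)
  ratio <- vapply(1:10, function(r) {
    tre <- rand_tree(200, 700 + r)
    tse <- sim_tips(tre, Q, 800 + r)
    f <- tryCatch(fit_mk(tre, tse, model = "ARD"),
                  error = function(e) NULL)
    if (is.null(f)) return(NA_real_)
    f$Q["a", "b"] / Q["a", "b"]
  }, numeric(1))
  expect_lte(median(ratio, na.rm = TRUE), 3)
  expect_gte(median(ratio, na.rm = TRUE), 1 / 3)

  expect_error(fit_mk(tr, setNames(rep("a", 80), tr$tip.label)),
               "unidentifiable")
})

test_that("stochastic maps are consistent and match marginal posteriors", {
  tr <- read_newick("((A:1,B:1):1,(C:0.5,D:0.5):1.5);")
  Q <- two_state_q(0.8, 0.5)
  ts <- c(A = "a", B = "b", C = "b", D = "a")
  maps <- stochastic_map(tr, ts, Q, 1000, seed = 99)

  # tip-end states equal observations; durations conserve branch lengths
  for (m in maps[1:50]) {
    expect_equal(vapply(m$maps, sum, numeric(1)), tr$edge.length,
                 tolerance = 1e-9)
    tip_end <- vapply(seq_len(nrow(tr$edge)), function(e)
      names(m$maps[[e]])[length(m$maps[[e]])], character(1))
    tips <- tr$edge[, 2] <= 4
    expect_equal(tip_end[tips], unname(ts[tr$tip.label[tr$edge[tips, 2]]]))
    # branch start state equals the sampled parent state
    ns <- attr(m, "node_states")
    starts <- vapply(seq_len(nrow(tr$edge)), function(e)
      names(m$maps[[e]])[1], character(1))
    expect_equal(starts, unname(ns[as.character(tr$edge[, 1])]))
  }

  # node-state frequencies approximate the pruning marginals
  marg <- mk_marginals(tr, ts, Q)
  freq_a <- rowMeans(vapply(maps, function(m)
    attr(m, "node_states")[5:7] == "a", logical(3)))
  expect_equal(unname(freq_a), unname(marg[5:7, "a"]), tolerance = 0.05)

  # total tree length conserved per map
  tot <- vapply(maps, function(m) sum(unlist(m$maps)), numeric(1))
  expect_equal(tot, rep(sum(tr$edge.length), 1000), tolerance = 1e-9)
})

test_that("zero rates give single-regime maps and clean summaries", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  Q0 <- two_state_q(0)
  maps <- stochastic_map(tr, c(A = "a", B = "a", C = "a"), Q0, 20,
                         seed = 3, root_prior = "uniform")
  s <- transition_summary(maps)
  expect_true(all(s$transitions == 0))
  expect_equal(unname(s$dwell["a"]), sum(tr$edge.length))

  # hand-built painting with one c -> i switch
  pt <- read_painting("(A:1[&regimes=c:1],B:1[&regimes=c:0.4|i:0.6]);",
                      c("c", "i"))
  s2 <- transition_summary(list(pt$painting))
  expect_equal(s2$transitions["c", "i"], 1)
  expect_equal(s2$transitions["i", "c"], 0)
  expect_equal(unname(s2$dwell), c(1.4, 0.6))
})
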