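make_net <- function(X_weights, confidence = "A") {
  # X_weights: gene x tf matrix of signed weights (0 = no edge)
  idx <- which(X_weights != 0, arr.ind = TRUE)
  data.frame(tf = colnames(X_weights)[idx[, 2]],
             target = rownames(X_weights)[idx[, 1]],
             weight = X_weights[idx], confidence = confidence)
}

test_that("orthogonal noiseless regulons are solved exactly", {
  # disjoint equal-size regulons plus unregulated genes (a full partition
  # would be aliased with the intercept)
  genes <- sprintf("g%02d", 1:40)
  W <- matrix(0, 40, 3, dimnames = list(genes, c("TFa", "TFb", "TFc")))
  W[1:10, 1] <- 1
  W[11:20, 2] <- 1
  W[21:30, 3] <- 1
  de <- data.frame(gene = genes, log2fc = c(rep(2, 10), rep(0, 30)))
  res <- tf_activity(de, make_net(W))
  expect_equal(res$coef[res$tf == "TFa"], 2, tolerance = 1e-10)
  expect_equal(res$coef[res$tf != "TFa"], c(0, 0), tolerance = 1e-10)
})

test_that("the fit equals a closed-form normal-equations oracle", {
  set.seed(30)
  for (rep in 1:20) {
    n_genes <- sample(15:50, 1)
    n_tf <- sample(2:5, 1)
    genes <- sprintf("g%03d", seq_len(n_genes))
    W <- matrix(0, n_genes, n_tf,
                dimnames = list(genes, sprintf("T%02d", seq_len(n_tf))))
    for (j in seq_len(n_tf)) {
      W[sample(n_genes, 6), j] <- sample(c(-1, 1), 6, TRUE)
    }
    y <- rnorm(n_genes)
    de <- data.frame(gene = genes, log2fc = y)
    res <- tryCatch(suppressWarnings(tf_activity(de, make_net(W))),
                    error = function(e) NULL)
    if (is.null(res) || nrow(res) < n_tf) next  # skip collinear draws
    X <- cbind(1, W)
    beta <- solve(crossprod(X), crossprod(X, y))
    sigma2 <- sum((y - X %*% beta)^2) / (n_genes - ncol(X))
    se <- sqrt(sigma2 * diag(solve(crossprod(X))))
    tstat <- beta / se
    ord <- match(res$tf, colnames(W))
    expect_equal(res$coef, unname(beta[-1][ord]), tolerance = 1e-8)
    expect_equal(res$t_stat, unname(tstat[-1][ord]), tolerance = 1e-8)
    expect_equal(res$pvalue,
                 unname(2 * pt(-abs(tstat[-1][ord]), n_genes - ncol(X))),
                 tolerance = 1e-8)
  }
})

test_that("confidence filtering, duplicates and collinearity are handled", {
  genes <- sprintf("g%02d", 1:20)
  W <- matrix(0, 20, 2, dimnames = list(genes, c("TFa", "TFlow")))
  W[1:8, 1] <- 1
  W[9:16, 2] <- 1
  net <- make_net(W)
  net$confidence <- ifelse(net$tf == "TFlow", "C", "A")
  set.seed(40)
  de <- data.frame(gene = genes, log2fc = rnorm(20))
  res <- tf_activity(de, net)
  expect_identical(res$tf, "TFa")   # C-confidence regulon excluded
  dup <- rbind(net, net[1, ])
  expect_error(tf_activity(de, dup), "duplicate")
  # perfectly collinear duplicated regulon is dropped with a warning
  W2 <- cbind(W, TFc = W[, 1])
  expect_warning(res2 <- tf_activity(de, make_net(W2)), "collinear")
  expect_lt(nrow(res2), 3)
})

test_that("a planted active TF ranks first on generator-derived fold changes", {
  de_spec <- data.frame(cell_type = "bulk", n_genes = 20L, lfc = 1.5,
                        frac_ligand = 0)
  wins <- 0
  n_seeds <- 5
  for (s in seq_len(n_seeds)) {
    sim <- generate_dataset(bulk_config(100 + s, n_genes = 400,
                                        mean_cells = 50, n_patients = 6,
                                        de_spec = de_spec))
    pb <- aggregate_pseudobulk(sim$matrix, min_counts = 0, min_cells = 1)
    de <- test_differential_expression(pb, "bulk")
    truth <- sim$truth
    truth$de_table$cell_type <- "bulk"
    net <- synthetic_regulons(rownames(sim$matrix), truth,
                              active_cell_type = "bulk", n_tfs = 6,
                              targets_per_tf = 15, seed = s)
    res <- tf_activity(de, net)
    wins <- wins + (res$tf[which.max(abs(res$t_stat))] == "TF_ACTIVE")
  }
  expect_identical(wins, n_seeds)
})

test_that("equalized top-N selection implements the lower-median rule", {
  mk_de <- function(n_sig, n_total = 400) {
    data.frame(gene = sprintf("g%03d", seq_len(n_total)),
               log2fc = c(rep(2, n_sig), rep(0.1, n_total - n_sig)),
               padj = c(seq_len(n_sig) * 1e-6, rep(0.5, n_total - n_sig)))
  }
  three <- list(a = mk_de(100), b = mk_de(182), c = mk_de(300))
  expect_identical(select_top_de(three)$n, 182L)
  two <- list(a = mk_de(4), b = mk_de(10))
  expect_identical(select_top_de(two)$n, 4L)
  # each list has exactly N genes when enough are tested
  out <- select_top_de(three)
  expect_true(all(lengths(out$genes) == 182L))
  # override wins
  expect_identical(select_top_de(two, top_n = 7)$n, 7)
  expect_error(select_top_de(list(a = mk_de(0))), "significant")
})

test_that("top-N ranking breaks ties by |lfc| then gene name", {
  de <- data.frame(gene = c("gB", "gA", "gC"),
                   log2fc = c(3, 1, 3),
                   padj = c(0.001, 0.001, 0.001))
  out <- select_top_de(list(x = de), fdr = 0.01, lfc_min = 0.5)
  expect_identical(out$genes$x, c("gB", "gC", "gA"))
})

test_that("ora matches the direct hypergeometric computation", {
  u <- sprintf("u%02d", 1:10)
  expect_equal(ora(u[1:3], u[1:3], u), 1 / choose(10, 3), tolerance = 1e-12)
  expect_equal(ora(u[1:3], character(), u), 1)
  expect_equal(ora(u[1:3], c("x", "y"), u), 1)   # set disjoint from universe
  expect_error(ora("a", "a", character()), "universe")
  expect_error(ora("zzz", u[1:2], u), "universe")
})

test_that("ora equals an enumeration oracle and is monotone in overlap", {
  tail_oracle <- function(k, m, n, draws) {
    # P(X >= k) by direct summation of hypergeometric terms
    xs <- max(k, max(0, draws - n)):min(m, draws)
    if (k > min(m, draws)) return(0)
    sum(choose(m, xs) * choose(n, draws - xs)) / choose(m + n, draws)
  }
  set.seed(33)
  for (i in 1:60) {
    N <- sample(8:25, 1)
    u <- sprintf("u%03d", seq_len(N))
    sel <- sample(u, sample(1:(N - 1), 1))
    gs <- sample(u, sample(1:N, 1))
    k <- length(intersect(sel, gs))
    expect_equal(ora(sel, gs, u),
                 tail_oracle(k, length(gs), N - length(gs), length(sel)),
                 tolerance = 1e-12)
  }
  # monotonicity at fixed margins
  u <- sprintf("u%03d", 1:40)
  ps <- sapply(0:10, function(k) {
    phyper(k - 1, 15, 25, 10, lower.tail = FALSE)
  })
  expect_true(all(diff(ps) <= 0))
  # gene order never matters
  sel <- u[1:8]; gs <- u[5:20]
  expect_equal(ora(sel, gs, u), ora(rev(sel), sample(gs), rev(u)))
})
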