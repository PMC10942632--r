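# Fixture: master on 5 species and gene trees derived from it by scaling /
# pruning, so expected branch-length cells are known exactly.
rer_fixture <- function() {
  master <- master5()
  genes <- list(
    full = master,
    double = {
      t2 <- master
      t2$edge.length <- 2 * t2$edge.length
      t2
    },
    noD = prune_to_species(master, c("A", "B", "C", "E"))
  )
  ts <- tree_set(master, genes)
  list(master = master, ts = ts)
}

test_that("branch-length matrix aligns gene branches to master keys", {
  fx <- rer_fixture()
  M <- build_branch_length_matrix(fx$ts)
  master_lens <- lengths_by_key(fx$master, fx$master)

  expect_equal(M["full", names(master_lens)], master_lens)
  expect_equal(M["double", names(master_lens)], 2 * master_lens)
  # gene missing one species of five: 2*4 - 2 = 6 non-missing cells
  expect_equal(sum(!is.na(M["noD", ])), 6)
  # and its pendant-E branch absorbed the collapsed (D,E) stem
  expect_equal(M["noD", "E"], master_lens[["E"]] + 1)
})

test_that("gene species sets are recoverable from singleton keys", {
  fx <- rer_fixture()
  M <- build_branch_length_matrix(fx$ts)
  sp <- matrix_gene_species(M)
  expect_setequal(sp$full, c("A", "B", "C", "D", "E"))
  expect_setequal(sp$noD, c("A", "B", "C", "E"))
})

test_that("shared branch keys of two pruned genes match a set-intersection oracle", {
  master <- read_newick("((((A:1,B:1):1,C:1):1,D:1):1,(E:1,F:1):2);")
  ga <- prune_to_species(master, c("A", "B", "C"))
  gb <- prune_to_species(master, c("C", "E", "F", "B"))
  ts <- tree_set(master, list(ga = ga, gb = gb))
  M <- build_branch_length_matrix(ts)
  shared <- colnames(M)[!is.na(M["ga", ]) & !is.na(M["gb", ])]
  # oracle: intersect the two genes' key sets computed independently
  oracle <- intersect(branch_keys(ga, master)$key, branch_keys(gb, master)$key)
  expect_setequal(shared, oracle)
  expect_setequal(shared, c("B", "C")) # the only branches both genes carry
})

test_that("master length estimation is exact for identical genes and scale families", {
  fx <- rer_fixture()
  master_lens <- lengths_by_key(fx$master, fx$master)
  ts_same <- tree_set(fx$master, list(g1 = fx$master, g2 = fx$master))
  m <- estimate_master_lengths(build_branch_length_matrix(ts_same))
  expect_equal(m[names(master_lens)], master_lens, tolerance = 1e-12)

  # genes at 1x and 3x the master: recovered up to one global constant
  t3 <- fx$master; t3$edge.length <- 3 * t3$edge.length
  ts_scaled <- tree_set(fx$master, list(g1 = fx$master, g3 = t3))
  m2 <- estimate_master_lengths(build_branch_length_matrix(ts_scaled))
  ratio <- m2[names(master_lens)] / master_lens
  expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-12)
})

test_that("master length estimation matches a two-pass recomputation with missing cells", {
  M <- matrix(
    c(
      1, 2, 3, 4,
      2, 4, 6, NA,
      1, 1, 1, 1
    ),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("g1", "g2", "g3"), c("A", "B", "A;B", "C"))
  )
  # two-pass oracle, spelled out cell by cell
  m0 <- c((1 + 2 + 1) / 3, (2 + 4 + 1) / 3, (3 + 6 + 1) / 3, (4 + 1) / 2)
  s <- c(
    10 / sum(m0),
    12 / sum(m0[1:3]),
    4 / sum(m0)
  )
  expected <- c(
    mean(c(1 / s[1], 2 / s[2], 1 / s[3])),
    mean(c(2 / s[1], 4 / s[2], 1 / s[3])),
    mean(c(3 / s[1], 6 / s[2], 1 / s[3])),
    mean(c(4 / s[1], 1 / s[3]))
  )
  m <- estimate_master_lengths(M)
  expect_equal(unname(m), expected, tolerance = 1e-12)
  expect_error(
    estimate_master_lengths(matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "X"))),
    "no gene covers"
  )
})

test_that("RERs are zero for proportional genes and centred per gene", {
  fx <- rer_fixture()
  # genes proportional to the estimated master lengths: estimate from a
  # scale family so the estimate itself is proportional to every gene
  master <- fx$master
  t2 <- master; t2$edge.length <- 2 * t2$edge.length
  ts <- tree_set(master, list(full = master, double = t2))
  M <- build_branch_length_matrix(ts)
  m <- estimate_master_lengths(M)
  for (method in c("log-ratio", "residual")) {
    R <- compute_rer(M, m, method = method)
    expect_lt(max(abs(R)), 1e-9)
  }

  # centring and missingness propagation, with a non-proportional gene mixed in
  Mfull <- build_branch_length_matrix(fx$ts)
  mfull <- estimate_master_lengths(Mfull)
  for (method in c("log-ratio", "residual")) {
    R <- compute_rer(Mfull, mfull, method = method)
    expect_lt(max(abs(rowMeans(R, na.rm = TRUE))), 1e-9)
    expect_equal(is.na(R), is.na(Mfull))
  }
  expect_error(compute_rer(Mfull, mfull, method = "bogus"))
})

test_that("a single accelerated branch gets positive RER, others negative", {
  master <- master5()
  fast <- master
  b <- 3L
  fast$edge.length[b] <- 2 * fast$edge.length[b]
  ts <- tree_set(master, list(ref1 = master, ref2 = master, fast = fast))
  M <- build_branch_length_matrix(ts)
  R <- compute_rer(M, estimate_master_lengths(M))
  fast_key <- branch_keys(fast, master)$key[b]
  expect_gt(R["fast", fast_key], 0)
  expect_true(all(R["fast", setdiff(colnames(R), fast_key)] < 0))
})

test_that("log-ratio RERs match the closed form on a 4-branch toy", {
  l <- c(0.4, 0.1, 0.3, 0.2)
  m <- c(0.2, 0.1, 0.2, 0.1)
  M <- matrix(l, 1, 4, dimnames = list("g", c("A", "B", "A;B", "C")))
  s <- sum(l) / sum(m)
  expected <- log(l / (s * m))
  expected <- expected - mean(expected)
  R <- compute_rer(M, stats::setNames(m, colnames(M)))
  expect_equal(unname(R["g", ]), expected, tolerance = 1e-9)
})

test_that("RERs are invariant to rescaling one gene's lengths", {
  set.seed(42)
  m <- stats::setNames(stats::runif(8, 0.05, 1), c(letters[1:6], "a;b", "c;d"))
  base <- m * exp(stats::rnorm(8, 0, 0.4))
  for (c_scale in c(0.5, 3, 10)) {
    M <- rbind(g1 = base, g2 = c_scale * base)
    R <- compute_rer(M, m)
    expect_equal(unname(R["g1", ]), unname(R["g2", ]), tolerance = 1e-9)
  }
})

test_that("both RER methods vanish together as noise goes to zero", {
  set.seed(7)
  m <- stats::setNames(stats::runif(10, 0.05, 1), c(letters[1:8], "a;b", "c;d"))
  M <- t(vapply(1:4, function(g) {
    g * m * exp(stats::rnorm(10, 0, 1e-5))
  }, numeric(10)))
  rownames(M) <- paste0("g", 1:4)
  for (method in c("log-ratio", "residual")) {
    R <- compute_rer(M, m, method = method)
    expect_lt(max(abs(R)), 1e-3)
  }
})

test_that("branch matrix TSV round-trips", {
  fx <- rer_fixture()
  M <- build_branch_length_matrix(fx$ts)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_branch_matrix_tsv(M, path)
  M2 <- read_branch_matrix_tsv(path)
  expect_equal(M2, M)
})
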