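test_that("default scheme gives 200 bins and validates divisibility", {
  sc <- bin_scheme()
  expect_equal(sc$n_bins, 200L)
  expect_equal(sc$half_window, 5000L)
  expect_error(bin_scheme(5000, 33), "divide")
})

test_that("reads land in the bin given by the index arithmetic", {
  # site center 5000 -> window [0, 10000); read anchored at 5025 -> bin 100
  site <- gr0("chr1", 4990, 5010)
  read <- gr0("chr1", 5025, 5026)
  m <- count_in_bins(read, site)
  expect_equal(sum(m$counts), 1)
  expect_equal(m$bin_index[m$counts[, 1] == 1], 100L)

  # zero reads -> all-zero matrix; empty sites -> error
  m0 <- count_in_bins(GenomicRanges::GRanges(), site)
  expect_true(all(m0$counts == 0))
  expect_error(count_in_bins(read, GenomicRanges::GRanges()), "empty site")
})

test_that("sites with out-of-bounds windows are dropped with a message", {
  lay <- genome_layout(c(chr1 = 20000))
  sites <- gr0("chr1", c(100, 9990), c(120, 10010))  # first window < 0
  expect_message(m <- count_in_bins(gr0("chr1", 0, 1), sites, layout = lay),
                 "dropped")
  expect_length(m$site_ids, 1)
})

test_that("window counts use a half-open right edge and report the mean", {
  sites <- gr0("chr1", c(990, 1990, 2990), c(1010, 2010, 3010))  # centers 1000/2000/3000
  reads <- gr0("chr1", c(1150, 1200, 2805), c(1151, 1201, 2806))
  res <- count_in_window(reads, sites, half_width = 200)
  # 1150 in [800,1200) counted; 1200 excluded; 2805 in [2800,3200) counted
  expect_equal(unname(res$counts), c(1, 0, 1))
  expect_equal(res$mean, sum(res$counts) / 3)
})

test_that("size factors reproduce the worked median-of-ratios example", {
  M <- matrix(c(2, 4, 6, 8, 16, 24), ncol = 2)
  s <- normchip_size_factors(M)
  expect_equal(as.vector(s), c(0.5, 2.0), tolerance = 1e-12)
  norm <- normchip_apply(M, s)
  expect_equal(norm[, 1], c(4, 8, 12))
  expect_equal(norm[, 2], c(4, 8, 12))

  # identical columns -> unit factors; zero rows are excluded
  expect_equal(as.vector(normchip_size_factors(cbind(1:3, 1:3))), c(1, 1))
  Mz <- rbind(c(0, 0), c(4, 16), c(6, 24))
  expect_message(sz <- normchip_size_factors(Mz), "excluded")
  expect_equal(as.vector(sz), c(0.5, 2.0), tolerance = 1e-12)
  expect_equal(attr(sz, "n_rows_used"), 2L)

  expect_error(normchip_size_factors(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(normchip_size_factors(rbind(c(0, 1), c(1, 0))), "pseudocount")
  expect_error(normchip_apply(M, c(1, 0)), "> 0")
})

test_that("size factors agree with an independent naive oracle on random matrices", {
  set.seed(500)
  for (k in 1:100) {
    nr <- sample(5:40, 1); nc <- sample(2:6, 1)
    M <- matrix(rpois(nr * nc, lambda = 20) + (runif(nr * nc) < 0.9),
                nr, nc)
    if (!any(apply(M, 1, function(r) all(r > 0)))) next
    got <- suppressMessages(normchip_size_factors(M))
    expect_equal(as.vector(got), naive_size_factors(M), tolerance = 1e-12)
  }
})

test_that("normalization is an algebraic fixed point", {
  set.seed(9)
  M <- matrix(rpois(600, 30) + 1, ncol = 3)
  s <- normchip_size_factors(M)
  norm <- normchip_apply(M, s)
  s2 <- normchip_size_factors(norm)
  expect_true(max(abs(s2 - s2[1])) < 1e-10)
  # each equals the geometric mean of the original factors
  expect_equal(as.vector(s2), rep(exp(mean(log(s))), 3), tolerance = 1e-10)
  # identity when s is all ones
  expect_equal(normchip_apply(M, c(1, 1, 1)), M)
})

test_that("size factors are permutation-equivariant", {
  set.seed(10)
  M <- matrix(rpois(500, 25) + 1, ncol = 5)
  s <- normchip_size_factors(M)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(as.vector(normchip_size_factors(M[, perm])), as.vector(s)[perm],
               tolerance = 1e-12)
  rperm <- sample(nrow(M))
  expect_equal(as.vector(normchip_size_factors(M[rperm, ])), as.vector(s),
               tolerance = 1e-12)
})

test_that("planted scale factors are recovered from Poisson signal", {
  sim <- simulate_signal(
    n_sites = 50, scheme = bin_scheme(),
    experiments = data.frame(label = c("a", "b", "c"),
                             size_factor = c(1, 2.5, 0.4),
                             profile = "bump"),
    baseline = 15, seed = 2024)
  s <- suppressMessages(normchip_size_factors(sim))
  gm <- function(x) exp(mean(log(x)))
  planted <- c(1, 2.5, 0.4)
  expect_lt(max(abs(s / gm(s) - planted / gm(planted)) /
                  (planted / gm(planted))), 0.02)
})

test_that("profile averaging matches brute-force grouped means", {
  m <- cbind(a1 = c(0, 2), a2 = c(2, 0), b = c(5, 5))
  avg <- average_profiles(m, c("a", "a", "b"))
  expect_equal(avg[, "a"], c(1, 1))
  expect_equal(avg[, "b"], c(5, 5))
  expect_equal(average_profiles(cbind(x = 1:3, y = 1:3),
                                c("g", "g"))[, "g"], as.numeric(1:3))
  set.seed(3)
  M <- matrix(runif(80), ncol = 8)
  g <- sample(letters[1:3], 8, replace = TRUE)
  avg <- average_profiles(M, g)
  for (k in unique(g)) {
    expect_equal(avg[, k], rowMeans(M[, g == k, drop = FALSE]))
  }
  expect_error(average_profiles(M, c("a", "b")), "one entry per column")
})

test_that("two-step normalization removes planted scales and is order-invariant", {
  # one factor, one context, two replicates differing by a planted 2x scale
  base <- matrix(rpois(400, 30) + 1, ncol = 1)
  M <- bin_count_matrix(cbind(r1 = base[, 1], r2 = 2 * base[, 1]),
               experiments = data.frame(label = c("r1", "r2"),
                                        factor = "f", context = "c1"))
  out <- suppressWarnings(two_step_normalize(M))
  expect_equal(ncol(out$counts), 1)
  # step-1 columns equal after scaling, so the average equals either
  expect_equal(out$counts[, 1] / sqrt(2), base[, 1], tolerance = 1e-10)

  # two factors already on a common scale: step 2 near-identity
  set.seed(77)
  shared <- rpois(400, 40) + 1
  M2 <- bin_count_matrix(cbind(fa = shared + rpois(400, 5),
                      fb = shared + rpois(400, 5)),
                experiments = data.frame(label = c("fa", "fb"),
                                         factor = c("A", "B"),
                                         context = "c1"))
  out2 <- suppressWarnings(two_step_normalize(M2))
  s_resid <- normchip_size_factors(out2$counts)
  expect_lt(max(abs(s_resid - 1)), 0.01)

  # permuting experiment order leaves outputs unchanged
  M3 <- bin_count_matrix(cbind(x = rpois(400, 20) + 1, y = rpois(400, 25) + 1,
                      z = rpois(400, 30) + 1),
                experiments = data.frame(label = c("x", "y", "z"),
                                         factor = c("A", "A", "B"),
                                         context = c("c1", "c1", "c1")))
  perm <- c(3, 1, 2)
  M3p <- bin_count_matrix(M3$counts[, perm],
                 experiments = M3$experiments[perm, ])
  o1 <- suppressWarnings(two_step_normalize(M3))
  o2 <- suppressWarnings(two_step_normalize(M3p))
  expect_equal(o1$counts, o2$counts)
  expect_warning(two_step_normalize(M3), "single dataset")
})

test_that("matrix TSV round trip preserves counts and metadata shape", {
  sim <- simulate_signal(n_sites = 4, scheme = bin_scheme(250, 50),
                         seed = 8)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(sim, p)
  back <- read_count_matrix(p)
  expect_equal(unname(back$counts), unname(sim$counts))
  expect_equal(back$site_ids, sim$site_ids)
  expect_equal(back$n_bins, sim$n_bins)
})
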