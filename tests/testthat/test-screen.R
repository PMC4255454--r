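test_that("tertile bins split samples into equal thirds deterministically", {
  b <- suppressWarnings(tertile_bins(9:1))
  expect_identical(sort(b$low_idx), 7:9)     # values 1,2,3
  expect_identical(sort(b$mid_idx), 4:6)
  expect_identical(sort(b$high_idx), 1:3)
  expect_false(b$binary)

  # n = 73: remainder goes to the low bin first -> sizes 25/24/24
  b73 <- tertile_bins(rnorm(73))
  expect_identical(lengths(b73[c("low_idx", "mid_idx", "high_idx")],
                           use.names = FALSE), c(25L, 24L, 24L))
  expect_identical(sort(unname(unlist(
    b73[c("low_idx", "mid_idx", "high_idx")]))), 1:73)
  expect_true(all(b73$boundaries == sort(b73$boundaries)))

  # ties resolved by original index order
  suppressWarnings(bt <- tertile_bins(rep(1, 12)))
  expect_identical(bt$low_idx, 1:4)
  expect_identical(bt$mid_idx, 5:8)
  expect_identical(bt$high_idx, 9:12)

  expect_error(tertile_bins(rnorm(8)), "at least 9")
  expect_warning(tertile_bins(rnorm(12)), "fewer than 15")
})

test_that("missing controller values are excluded from the bins", {
  x <- c(rnorm(45), NA, NA)
  b <- tertile_bins(x)
  expect_identical(b$n, 45L)
  expect_false(any(c(46L, 47L) %in%
                     unlist(b[c("low_idx", "mid_idx", "high_idx")])))
})

test_that("binary controllers become two groups", {
  x <- rep(c(0, 1), c(20, 25))
  b <- tertile_bins(x)
  expect_true(b$binary)
  expect_identical(b$low_idx, 1:20)
  expect_identical(b$high_idx, 21:45)
  expect_length(b$mid_idx, 0)
})

test_that("rho_diff matrix matches the per-pair brute-force oracle", {
  set.seed(31)
  m <- simulate_null(10, 21, seed = 31)
  genes <- rownames(m)
  for (ctrl in genes[c(1, 5, 10)]) {
    D <- suppressWarnings(rho_diff_for_controller(m, ctrl))
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (pair in list(c(2, 3), c(1, 9), c(4, 8))) {
      g <- genes[pair]
      if (ctrl %in% g) next
      expect_equal(D[g[1], g[2]], oracle_rho_diff(m, g[1], g[2], ctrl),
                   tolerance = 1e-10)
    }
  }
})

test_that("rho_diff attains its extremes and handles degeneracies", {
  set.seed(32)
  # identical genes: rho 1 in both bins -> diff 0
  m <- simulate_null(4, 45, seed = 32)
  m["g0002", ] <- m["g0001", ]
  D <- rho_diff_for_controller(m, "g0004")
  expect_equal(D["g0001", "g0002"], 0)
  # pair flipping from perfect anti- to perfect correlation -> diff 2
  x3 <- sort(rnorm(45))
  b <- tertile_bins(x3)
  x1 <- rnorm(45)
  x2 <- x1
  x2[b$low_idx] <- -x1[b$low_idx]
  m2 <- rbind(a = x1, b = x2, cc = rnorm(45), z = x3)
  D2 <- rho_diff_for_controller(m2, "z")
  expect_equal(D2["a", "b"], 2)
  # zero within-bin variance gene flagged NA with a message
  m3 <- simulate_null(4, 45, seed = 33)
  m3["g0002", ] <- 1          # constant everywhere
  expect_message(D3 <- rho_diff_for_controller(m3, "g0004"), "undefined")
  expect_true(all(is.na(D3["g0002", c("g0001", "g0003")])))
  expect_false(anyNA(D3["g0001", "g0003"]))
})

test_that("negating the controller negates rho_diff (tie-free, n %% 3 == 0)", {
  m <- simulate_null(6, 45, seed = 34)
  D <- rho_diff_for_controller(m, "g0006")
  Dn <- rho_diff_for_controller(rbind(m[-6, ], g0006 = -m["g0006", ]),
                                "g0006")
  expect_equal(D[-6, -6], -Dn[-6, -6], tolerance = 1e-12)
})

test_that("screen output equals exhaustive enumeration and nests in the threshold", {
  m <- simulate_null(12, 45, seed = 35)
  hits <- screen_all(m, threshold = 0.5)
  ora <- oracle_screen(m, 0.5)
  key <- function(d) sort(paste(d$x1, d$x2, d$x3))
  expect_identical(key(hits), key(ora))
  expect_equal(hits$rho_diff, hits$rho_high - hits$rho_low, tolerance = 1e-12)
  expect_true(all(hits$x1 < hits$x2))
  expect_true(all(hits$x3 != hits$x1 & hits$x3 != hits$x2))
  # values agree with the oracle too
  mrg <- merge(hits, ora, by = c("x1", "x2", "x3"))
  expect_equal(mrg$rho_diff.x, mrg$rho_diff.y, tolerance = 1e-10)
  # monotone nesting of hit sets
  prev <- key(hits)
  for (th in c(0.7, 0.9, 1.2)) {
    cur <- key(screen_all(m, threshold = th))
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # impossible cutoff
  expect_identical(nrow(screen_all(m, threshold = 2)), 0L)
})

test_that("a planted strong liquid-association triplet is screened in", {
  m <- make_planted_matrix(G = 10, N = 300, c1 = 2, seed = 41)
  hits <- screen_all(m, threshold = 0.5)
  row <- hits[hits$x1 == "g0001" & hits$x2 == "g0002" & hits$x3 == "g0003", ]
  expect_identical(nrow(row), 1L)
  # tanh(2z) is near +-1 in the outer tertiles -> rho_diff near 2
  expect_gt(row$rho_diff, 1.5)
})

test_that("rho_diff stays within [-2, 2] and is symmetric on null data", {
  m <- simulate_null(15, 45, seed = 42)
  hits <- screen_all(m, threshold = 0.05)
  expect_true(all(hits$rho_diff >= -2 & hits$rho_diff <= 2))
  # on i.i.d. data the rho_diff distribution is centred at 0
  D <- rho_diff_for_controller(m, "g0001")
  vals <- D[upper.tri(D)][row(D)[upper.tri(D)] != 1 & col(D)[upper.tri(D)] != 1]
  expect_lt(abs(mean(vals)) / (sd(vals) / sqrt(length(vals))), 4)
})

test_that("spearman mode matches rank-transformed pearson", {
  m <- simulate_null(6, 45, seed = 43)
  Ds <- rho_diff_for_controller(m, "g0006", method = "spearman")
  b <- tertile_bins(m["g0006", ])
  manual <- cor(t(apply(m[, b$high_idx], 1, rank))["g0001", ],
                t(apply(m[, b$high_idx], 1, rank))["g0002", ]) -
    cor(rank(m["g0001", b$low_idx]), rank(m["g0002", b$low_idx]))
  expect_equal(Ds["g0001", "g0002"], manual, tolerance = 1e-12)
})

test_that("triplet count follows G(G-1)(G-2)/2", {
  expect_identical(count_triplets(3), 3)
  expect_identical(count_triplets(10), 360)
  expect_identical(count_triplets(10), 3 * choose(10, 3))
  expect_error(count_triplets(2), "at least 3")
})
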