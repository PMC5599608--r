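test_that("cluster mean/variance surfaces match hand arithmetic", {
  grid <- tinyGrid()
  set.seed(61)
  mk <- function() {
    pts <- cbind(runif(25, 1300, 4700), runif(25, 100, 3500))
    kdeSurface(pts, diag(c(600^2, 600^2)), grid)
  }
  surfs <- list(A = mk(), B = mk(), C = mk())
  w <- c(A = 0.5, B = 0.3, C = 0.2)
  mv <- clusterMeanVar(surfs, w)
  mu <- 0.5 * surfs$A@values + 0.3 * surfs$B@values + 0.2 * surfs$C@values
  v <- 0.5 * (surfs$A@values - mu)^2 + 0.3 * (surfs$B@values - mu)^2 +
       0.2 * (surfs$C@values - mu)^2
  expect_equal(mv$mean, mu, tolerance = 1e-12)
  expect_equal(mv$var, v, tolerance = 1e-12)
  expect_equal(mv$n_animals, 3)
})

test_that("variance model recovers a power-law mean-variance relation", {
  # simulate var = a * mean^b on synthetic clusters and refit
  grid <- tinyGrid()
  set.seed(62)
  a <- exp(-2); b <- 1.6
  cluster_surfaces <- list(); weights <- list()
  # build three fake 'clusters' whose per-animal surfaces have controlled spread
  for (ci in 1:3) {
    sea <- which(!grid@land)
    mu <- runif(length(sea)); mu <- mu / sum(mu)
    surfs <- list()
    n_an <- 6 + ci
    for (aa in 1:n_an) {
      noise <- rnorm(length(sea), 0, sqrt(a * mu^b))
      v <- pmax(mu + noise, 0)
      vals <- matrix(0, grid@nrow, grid@ncol)
      vals[sea] <- v / sum(v)
      surfs[[sprintf("A%d%d", ci, aa)]] <-
        new("UsageSurface", grid = grid, values = vals,
            normalisation = "per-animal")
    }
    cluster_surfaces[[sprintf("c%d", ci)]] <- surfs
    weights[[sprintf("c%d", ci)]] <-
      setNames(rep(1 / n_an, n_an), names(surfs))
  }
  vm <- fitVarianceModel(cluster_surfaces, weights, min_animals = 7)
  # slope on log mean should sit near the generative exponent
  expect_equal(unname(vm@coefficients["log_mean"]), b, tolerance = 0.2 * b)
  # prediction is positive everywhere at sea and zero on land
  pred <- predictVariance(vm, cluster_surfaces[["c1"]][[1]], n_animals = 7)
  expect_true(all(pred[!grid@land] > 0))
  expect_true(all(pred[grid@land] == 0))
})

test_that("variance model demands at least two data-rich clusters", {
  grid <- tinyGrid()
  s <- new("UsageSurface", grid = grid,
           values = {
             v <- matrix(0, grid@nrow, grid@ncol)
             sea <- which(!grid@land); v[sea] <- 1 / length(sea); v
           },
           normalisation = "per-animal")
  cs <- list(c1 = list(A = s, B = s), c2 = list(C = s))
  w <- list(c1 = c(A = 0.5, B = 0.5), c2 = c(C = 1))
  # only c1 is data-rich at min_animals = 2 -> error
  expect_error(fitVarianceModel(cs, w, min_animals = 2), "lowering min_animals")
  # two data-rich clusters suffice, but the small study is flagged
  set.seed(61)
  mk <- function() {
    pts <- cbind(runif(25, 1300, 4700), runif(25, 100, 3500))
    kdeSurface(pts, diag(c(700^2, 700^2)), grid)
  }
  cs2 <- list(c1 = list(A = mk(), B = mk()), c2 = list(C = mk(), D = mk()))
  w2 <- list(c1 = c(A = 0.4, B = 0.6), c2 = c(C = 0.5, D = 0.5))
  expect_message(vm <- fitVarianceModel(cs2, w2, min_animals = 2),
                 "poorly constrained")
  expect_s4_class(vm, "VarianceModel")
})

test_that("population bootstrap matches a quadrature oracle for E[N] and Var[N]", {
  count <- 120; m <- 0.72; s <- 0.05
  v <- m * (1 - m) / s^2 - 1
  shape1 <- m * v; shape2 <- (1 - m) * v
  # oracle: moments of count/p under the (clamped) beta by quadrature
  f1 <- function(p) count / pmin(pmax(p, 0.01), 0.99) * dbeta(p, shape1, shape2)
  f2 <- function(p) (count / pmin(pmax(p, 0.01), 0.99))^2 * dbeta(p, shape1, shape2)
  e1 <- integrate(f1, 0, 1, rel.tol = 1e-10)$value
  e2 <- integrate(f2, 0, 1, rel.tol = 1e-10)$value
  pe <- populationEstimate(count, c(m, s), n_boot = 200000, seed = 9)
  expect_equal(pe$mean, e1, tolerance = 0.005 * e1)
  expect_equal(pe$variance, e2 - e1^2, tolerance = 0.05 * (e2 - e1^2))
  # zero-sd shortcut
  p0 <- populationEstimate(count, c(m, 0))
  expect_equal(p0$mean, count / m)
  expect_equal(p0$variance, 0)
  # impossible beta moments fall back with a warning
  expect_warning(populationEstimate(count, c(0.5, 0.6), n_boot = 100, seed = 1),
                 "logit-normal")
})

test_that("variance combination matches a Monte-Carlo oracle", {
  set.seed(63)
  grid <- tinyGrid()
  sea <- which(!grid@land)
  u <- matrix(0, grid@nrow, grid@ncol)
  u[sea] <- runif(length(sea)); u <- u / sum(u)
  usage <- new("UsageSurface", grid = grid, values = u,
               normalisation = "per-cluster")
  s2u <- matrix(0, grid@nrow, grid@ncol)
  s2u[sea] <- (u[sea] / 4)^2
  pop <- list(mean = 150, variance = 900)
  f <- 0.7
  sc <- scaleAndCombine(usage, s2u, pop, f)
  expect_equal(sc$mean, 150 * f * u, tolerance = 1e-12)
  # MC oracle at a specific cell: Var(f * N * U) with N, U independent
  cell <- sea[10]
  N <- rnorm(400000, 150, 30)
  U <- rnorm(400000, u[cell], sqrt(s2u[cell]))
  expect_equal(sc$variance[cell], var(f * N * U), tolerance = 0.02)
  expect_true(all(sc$lower <= sc$mean + 1e-12))
  expect_true(all(sc$upper >= sc$mean - 1e-12))
  expect_true(all(sc$lower >= 0))
})

test_that("at-sea fraction weighs animals equally and matches the bout geometry", {
  # renewal argument: mean trip 12 steps vs mean haul bout 6 steps -> 2/3
  gw <- fixtureWorld()
  tr <- simulateTracks(gw$world, n_animals = 8, mean_lifespan_h = 8000,
                       seed = 64)
  tracks <- regulariseTrack(cleanseFixes(tr$fixes))
  fr <- atSeaFraction(tracks)
  expect_equal(fr$overall, 2 / 3, tolerance = 0.05)
  expect_equal(fr$overall, mean(fr$per_animal$at_sea))
  pc <- atSeaFraction(tracks,
                      cluster_animals = list(c1 = fr$per_animal$animal_id[1:3]))
  expect_equal(pc$per_cluster[["c1"]], mean(fr$per_animal$at_sea[1:3]))
})
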