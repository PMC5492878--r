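two_class_gaussian <- function() {
  x <- matrix(c(-0.1, 0, 0.1, 0, 9.9, 10, 10.1, 10), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("A", "B"), each = 4)
  train_naive_bayes(x, y)
}

test_that("the Gaussian naive-Bayes boundary sits at the class midpoint", {
  m <- two_class_gaussian()
  expect_equal(unname(which.max(classify_instance(m, c(f = 4.9)))), 1)
  expect_equal(unname(which.max(classify_instance(m, c(f = 5.1)))), 2)
  expect_gt(classify_instance(m, c(f = 0))[["A"]], 0.999)
})

test_that("identical per-class feature distributions return the prior", {
  x <- matrix(rep(c(1, 2, 3, 4), 2), ncol = 1, dimnames = list(NULL, "f"))
  y <- rep(c("A", "B"), each = 4)
  m <- train_naive_bayes(x, y)
  post <- classify_instance(m, c(f = 2.5))
  expect_equal(unname(post), unname(m$priors), tolerance = 1e-9)
})

test_that("degenerate training sets are rejected", {
  x <- matrix(1:4, ncol = 1, dimnames = list(NULL, "f"))
  expect_error(train_naive_bayes(x, rep("A", 4)), "degenerate")
  expect_error(train_naive_bayes(x, c("A", "A", "A", "B")), "degenerate")
  expect_error(train_bayes_network(x, c("A", "B", "C", "D")), "degenerate")
})

test_that("posteriors normalise and stay finite, even outside the bin range", {
  set.seed(20)
  x <- matrix(rnorm(600), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rep(c("Wk", "Sd"), each = 100)
  x[y == "Sd", ] <- x[y == "Sd", ] + 2
  for (model in list(train_naive_bayes(x, y),
                     train_bayes_network(x, y, max_parents = 1))) {
    for (i in 1:20) {
      v <- c(f1 = rnorm(1, 0, 10), f2 = rnorm(1, 0, 10), f3 = rnorm(1, 0, 10))
      post <- classify_instance(model, v)
      expect_equal(sum(post), 1, tolerance = 1e-9)
      expect_true(all(is.finite(post)))
      expect_true(all(post > 0))
    }
    # values far outside every training bin still classify finitely
    post <- classify_instance(model, c(f1 = 1e6, f2 = -1e6, f3 = 0))
    expect_true(all(is.finite(post)))
  }
})

test_that("missing feature keys raise a schema error", {
  m <- two_class_gaussian()
  expect_error(classify_instance(m, c(g = 1)), "schema error.*f")
})

test_that("Eq-style factorised posterior matches brute-force joint enumeration", {
  # 2 features, 3 bins, 2 classes
  set.seed(21)
  n <- 150
  y <- rep(c("A", "B"), each = n)
  f1 <- c(rnorm(n, 0), rnorm(n, 1.5))
  f2 <- 0.8 * f1 + c(rnorm(n, 0, 0.5), rnorm(n, 0.5, 0.5))
  x <- cbind(f1 = f1, f2 = f2)
  m <- train_bayes_network(x, y, max_parents = 1, bins = 3)

  b1 <- seq_len(m$nbins[["f1"]])
  b2 <- seq_len(m$nbins[["f2"]])
  cpt_at <- function(f, b, k, assignment) {
    par <- m$parents[[f]]
    pidx <- if (length(par) == 0) 1L else assignment[[par]]
    m$cpt[[f]][b, k, pidx]
  }
  # total probability over all joint assignments is 1 for each class
  for (k in 1:2) {
    tot <- 0
    for (i in b1) for (j in b2) {
      a <- list(f1 = i, f2 = j)
      tot <- tot + cpt_at("f1", i, k, a) * cpt_at("f2", j, k, a)
    }
    expect_equal(tot, 1, tolerance = 1e-9)
  }
  # posterior of concrete instances matches the enumerated joint
  for (v in list(c(f1 = 0.2, f2 = 0.1), c(f1 = 1.4, f2 = 1.9),
                 c(f1 = -3, f2 = 5))) {
    i <- findInterval(v["f1"], m$breaks[["f1"]]) + 1
    j <- findInterval(v["f2"], m$breaks[["f2"]]) + 1
    a <- list(f1 = i, f2 = j)
    joint <- sapply(1:2, function(k) {
      m$priors[[k]] * cpt_at("f1", i, k, a) * cpt_at("f2", j, k, a)
    })
    expect_equal(unname(classify_instance(m, v)), joint / sum(joint),
                 tolerance = 1e-10)
  }
})

test_that("a parent-free network reproduces discretized naive Bayes exactly", {
  set.seed(22)
  x <- cbind(f1 = rnorm(200), f2 = rnorm(200, sd = 2))
  y <- rep(c("A", "B"), 100)
  x[y == "B", ] <- x[y == "B", ] + 1
  m0 <- train_bayes_network(x, y, max_parents = 0)
  expect_true(all(lengths(m0$parents) == 0))
  for (i in 1:10) {
    v <- c(f1 = rnorm(1), f2 = rnorm(1))
    expect_equal(unname(classify_instance(m0, v)),
                 unname(oracle_discrete_nb(x, y, v)),
                 tolerance = 1e-10)
  }
})

test_that("structure search finds a duplicated-feature dependence", {
  set.seed(23)
  n <- 500
  y <- rep(c("A", "B"), each = n)
  f1 <- c(rnorm(n, 0), rnorm(n, 2))
  x <- cbind(f1 = f1, f2 = f1)
  split <- c(sample(which(y == "A"), 350), sample(which(y == "B"), 350))
  bn <- train_bayes_network(x[split, ], y[split], max_parents = 1)
  linked <- "f1" %in% bn$parents[["f2"]] || "f2" %in% bn$parents[["f1"]]
  expect_true(linked)

  nb <- train_naive_bayes(x[split, ], y[split], likelihood = "discrete")
  acc <- function(m) {
    mean(predict(m, x[-split, ], type = "class") == y[-split])
  }
  expect_gte(acc(bn), acc(nb))
})

test_that("conditionally independent features score best with no feature edges", {
  set.seed(24)
  n <- 5000
  y <- rep(c("A", "B"), each = n / 2)
  x <- cbind(f1 = rnorm(n) + (y == "B"), f2 = rnorm(n) - (y == "B"))
  bn <- train_bayes_network(x, y, max_parents = 1)
  expect_equal(sum(lengths(bn$parents)), 0)
})

test_that("window aggregation rules and fall-biased tie-breaking", {
  x <- matrix(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), ncol = 1,
              dimnames = list(NULL, "f"))
  y <- rep(c("Wk", "Bw-Fall"), each = 50)
  m <- train_naive_bayes(x, y)

  all_wk <- matrix(rnorm(200, 0, 0.1), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(classify_window(m, all_wk, "majority"), "Wk")
  expect_equal(classify_window(m, all_wk, "mean_log_posterior"), "Wk")

  mixed <- matrix(c(rnorm(120, 10, 0.1), rnorm(80, 0, 0.1)), ncol = 1,
                  dimnames = list(NULL, "f"))
  expect_equal(classify_window(m, mixed, "majority"), "Bw-Fall")

  # exact 100/100 vote tie between an ADL and a fall alarms
  x2 <- matrix(c(rnorm(50, 0, 0.1), rnorm(50, 10, 0.1)), ncol = 1,
               dimnames = list(NULL, "f"))
  y2 <- rep(c("Sd", "Sd-Fall"), each = 50)
  m2 <- train_naive_bayes(x2, y2)
  tie <- matrix(rep(c(0, 10), each = 100), ncol = 1,
                dimnames = list(NULL, "f"))
  expect_equal(classify_window(m2, tie, "majority"), "Sd-Fall")

  expect_error(classify_window(m, x[0, , drop = FALSE]), "empty")
})

test_that("relabelling classes permutes the outputs correspondingly", {
  set.seed(25)
  x <- matrix(c(rnorm(60, 0), rnorm(60, 3), rnorm(60, 6)), ncol = 1,
              dimnames = list(NULL, "f"))
  y1 <- rep(c("Wk", "Sd", "Sq"), each = 60)
  map <- c(Wk = "Bw", Sd = "Wk", Sq = "Sd")
  m1 <- train_naive_bayes(x, y1)
  m2 <- train_naive_bayes(x, unname(map[y1]))
  probe <- matrix(seq(-1, 7, by = 0.5), ncol = 1, dimnames = list(NULL, "f"))
  p1 <- predict(m1, probe, type = "class")
  p2 <- predict(m2, probe, type = "class")
  expect_equal(unname(map[p1]), unname(p2))
})

test_that("models survive a serialisation round trip", {
  set.seed(26)
  x <- cbind(f1 = rnorm(200), f2 = rnorm(200))
  y <- rep(c("Wk", "Bw-Fall"), each = 100)
  x[y == "Bw-Fall", ] <- x[y == "Bw-Fall", ] + 2
  for (m in list(train_naive_bayes(x, y),
                 train_bayes_network(x, y, max_parents = 1))) {
    path <- withr::local_tempfile(fileext = ".yml")
    write_bayes_model(m, path)
    back <- read_bayes_model(path)
    probe <- cbind(f1 = c(-1, 0, 1, 3), f2 = c(0, 1, 2, 3))
    expect_equal(predict(back, probe, type = "posterior"),
                 predict(m, probe, type = "posterior"), tolerance = 1e-10)
  }
})
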