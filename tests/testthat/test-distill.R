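test_that("tempered softmax is overflow-safe and temperature-monotone", {
  expect_equal(softmax_t(c(3, 3, 3), 2), rep(1 / 3, 3))
  expect_equal(softmax_t(c(2, 0), 2), oracle_softmax(c(1, 0), 1),
               tolerance = 1e-12)
  expect_equal(softmax_t(c(1000, 0), 1), c(1, 0))
  expect_error(softmax_t(c(1, 2), 0), class = "attnkd_invalid_input")
  # max probability non-increasing in T
  set.seed(21)
  for (i in 1:10) {
    z <- rnorm(6, sd = 3)
    m <- vapply(c(1, 2, 4, 8), function(temp) max(softmax_t(z, temp)), 0)
    expect_true(all(diff(m) <= 1e-12))
  }
})

test_that("cross entropy handles confident, uniform, and floored cases", {
  expect_equal(cross_entropy(c(0, 1, 0), 1), 0)
  expect_equal(cross_entropy(rep(0.25, 4), 2), log(4))
  expect_equal(cross_entropy(c(0, 1), 0), -log(1e-12))
  expect_true(is.finite(cross_entropy(c(0, 1), 0)))
  expect_error(cross_entropy(c(0.5, 0.5), 2), class = "attnkd_invalid_input")
})

test_that("teacher loss bundle sums branch cross-entropies", {
  onehot <- c(1e-9, 1 - 2e-9, 1e-9)
  b <- teacher_total_loss(onehot, onehot, list(onehot, onehot), 1)
  expect_lt(b$l_total, 1e-6)

  p1 <- oracle_softmax(c(1, 2, 0), 1)
  p2 <- oracle_softmax(c(0, 1, 3), 1)
  b0 <- teacher_total_loss(p1, p2, list(), 2)
  expect_equal(b0$l_p, 0)
  expect_equal(b0$l_total, b0$l_r + b0$l_o)

  p3 <- oracle_softmax(c(2, 2, 2), 1)
  b3 <- teacher_total_loss(p1, p2, list(p3, p1), 0)
  expect_equal(b3$l_r, -log(p1[1]))
  expect_equal(b3$l_o, -log(p2[1]))
  expect_equal(b3$l_p, -log(p3[1]) - log(p1[1]))
  expect_equal(b3$l_total, b3$l_r + b3$l_o + b3$l_p)
  expect_error(teacher_total_loss(p1, p2[1:2], list(), 0),
               class = "attnkd_invalid_input")
})

test_that("kd loss is the tempered teacher-to-student KL divergence", {
  z <- c(1.3, -0.2, 0.8)
  expect_equal(kd_loss(z, z, 4), 0)
  # teacher (0.8, 0.2) vs student (0.5, 0.5) at T = 1
  zt <- c(log(0.8), log(0.2))
  zs <- c(0, 0)
  expect_equal(kd_loss(zt, zs, 1),
               0.8 * log(0.8 / 0.5) + 0.2 * log(0.2 / 0.5),
               tolerance = 1e-9)
  set.seed(8)
  for (i in 1:20) {
    a <- rnorm(5, sd = 3); b <- rnorm(5, sd = 3)
    expect_gte(kd_loss(a, b, sample(c(1, 2, 4), 1)), 0)
  }
})

test_that("binary split and non-target distribution follow their definitions", {
  expect_equal(unname(binary_split(c(1, 1), 0, 1)), c(0.5, 0.5))
  b <- binary_split(c(2, 0, 0), 0, 1)
  expect_equal(unname(b["p_t"]), exp(2) / (exp(2) + 2), tolerance = 1e-12)
  set.seed(9)
  for (i in 1:10) {
    z <- rnorm(7, sd = 2)
    bs <- binary_split(z, 3, 4)
    expect_equal(unname(sum(bs)), 1, tolerance = 1e-12)
  }

  expect_equal(nontarget_probs(c(5, 1), 0, 1), 1)
  expect_equal(nontarget_probs(c(0, 2, 2, 2), 0, 3), rep(1 / 3, 3))
  expect_equal(nontarget_probs(c(5, 2, 0), 0, 1), oracle_softmax(c(2, 0), 1),
               tolerance = 1e-12)
  # invariance to the target logit
  z <- c(5, 2, 0)
  z2 <- z; z2[1] <- -40
  expect_equal(nontarget_probs(z, 0, 1), nontarget_probs(z2, 0, 1),
               tolerance = 1e-12)
})

test_that("tckd and nckd are the KLs of their reduced distributions", {
  z <- c(0.4, -1, 2)
  expect_equal(tckd(z, z, 1, 4), 0)
  expect_equal(nckd(z, z, 1, 4), 0)

  # teacher split (0.9, 0.1) vs student (0.5, 0.5)
  zt <- c(log(0.9), log(0.1))
  zs <- c(0, 0)
  expect_equal(tckd(zt, zs, 0, 1), 0.9 * log(1.8) + 0.1 * log(0.2),
               tolerance = 1e-9)
  expect_equal(nckd(zt, zs, 0, 1), 0)  # two classes: both reduced to [1]

  set.seed(10)
  for (i in 1:20) {
    a <- rnorm(5, sd = 3); b <- rnorm(5, sd = 3); t <- sample(0:4, 1)
    expect_gte(tckd(a, b, t, 4), 0)
    expect_equal(nckd(a, b, t, 2),
                 oracle_kl(oracle_softmax(a[-(t + 1)], 2),
                           oracle_softmax(b[-(t + 1)], 2)),
                 tolerance = 1e-9)
  }
})

test_that("dkd decomposes classical kd exactly via the coupled weight", {
  z <- c(1, 2, 3)
  expect_equal(dkd_loss(z, z, 0, 4, 0.7)$total, 0)

  pairs <- gen_logit_pairs(C = 6, n = 200, seed = 77)
  for (p in pairs) for (temp in c(1, 2, 4)) {
    b <- dkd_loss(p$z_teacher, p$z_student, p$target, T = temp, alpha = 2)
    expect_equal(b$total, b$tckd + 2 * b$nckd, tolerance = 1e-12)
    expect_equal(kd_loss(p$z_teacher, p$z_student, temp),
                 b$tckd + (1 - b$teacher_pt) * b$nckd, tolerance = 1e-9)
  }

  # alpha = 2 on a fixed pair equals separately computed parts
  zt <- c(3, 1, -1); zs <- c(0.5, 1.5, 0)
  b <- dkd_loss(zt, zs, 0, T = 4, alpha = 2)
  expect_equal(b$total, tckd(zt, zs, 0, 4) + 2 * nckd(zt, zs, 0, 4),
               tolerance = 1e-12)
  expect_error(dkd_loss(zt, zs, 0, 4, -1), class = "attnkd_invalid_input")
})

test_that("student stream loss is additive with the documented reduction", {
  conf <- c(12, 0, 0)
  s1 <- list(z_student = conf, z_teacher = conf, label = 0)
  b1 <- student_total_loss(list(s1), T = 4, alpha = 2)
  expect_lt(b1$l_total, 1e-4)

  set.seed(15)
  st <- list(z_student = rnorm(4), z_teacher = rnorm(4), label = 2)
  one <- student_total_loss(list(st), T = 4, alpha = 2)
  two <- student_total_loss(list(st, st), T = 4, alpha = 2)
  expect_equal(two$l_hard, 2 * one$l_hard, tolerance = 1e-12)
  expect_equal(two$l_soft, 2 * one$l_soft, tolerance = 1e-12)

  streams <- lapply(1:3, function(i)
    list(z_student = rnorm(5), z_teacher = rnorm(5), label = i - 1))
  b <- student_total_loss(streams, T = 4, alpha = 2)
  hard <- sum(vapply(streams, function(s)
    -log(oracle_softmax(s$z_student, 1)[s$label + 1]), 0))
  soft <- sum(vapply(streams, function(s)
    dkd_loss(s$z_teacher, s$z_student, s$label, 4, 2)$total, 0))
  expect_equal(b$l_hard, hard, tolerance = 1e-9)
  expect_equal(b$l_soft, soft, tolerance = 1e-9)
  expect_equal(b$l_total, b$l_hard + b$l_soft)

  # "kd" mode reproduces the classical loss; "none" drops the soft term
  bkd <- student_total_loss(streams, T = 4, soft_mode = "kd")
  expect_equal(bkd$l_soft,
               sum(vapply(streams, function(s)
                 kd_loss(s$z_teacher, s$z_student, 4), 0)),
               tolerance = 1e-9)
  expect_equal(student_total_loss(streams, soft_mode = "none")$l_soft, 0)
})

test_that("analytic dkd gradient matches numerical differentiation", {
  set.seed(23)
  for (i in 1:10) {
    C <- sample(3:7, 1)
    zt <- rnorm(C, sd = 2)
    zs <- rnorm(C, sd = 2)
    tg <- sample(0:(C - 1), 1)
    temp <- sample(c(1, 4), 1)
    for (mode in c("dkd", "kd")) {
      al <- if (mode == "dkd") runif(1, 0, 3) else 2
      f <- function(z) {
        b <- dkd_loss(zt, z, tg, temp, alpha = 1)
        w <- if (mode == "kd") 1 - b$teacher_pt else al
        b$tckd + w * b$nckd
      }
      expect_equal(attnkd:::dkd_grad_student(zt, zs, tg, temp, al, mode),
                   numerical_grad(f, zs), tolerance = 1e-5)
    }
  }
  # classical-kd gradient equals (s - t) / T
  zt <- c(2, -1, 0.5); zs <- c(0, 1, -0.5)
  expect_equal(attnkd:::dkd_grad_student(zt, zs, 1, 4, 2, "kd"),
               (oracle_softmax(zs, 4) - oracle_softmax(zt, 4)) / 4,
               tolerance = 1e-9)
})
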