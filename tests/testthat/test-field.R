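test_that("kernel_eval matches the closed forms and rejects bad input", {
  expect_equal(kernel_eval(signal_kernel("poly", 2), 1), 1)
  expect_equal(kernel_eval(signal_kernel("poly", 2), 2), 0.25)
  expect_equal(kernel_eval(signal_kernel("exp", 11), 0.5), exp(-5.5))
  expect_equal(kernel_eval(signal_kernel("poly", 0.5), 4), 0.5)

  expect_error(kernel_eval(signal_kernel("poly", 2), 0), "positive")
  expect_error(kernel_eval(signal_kernel("poly", 2), -1), "positive")
  expect_error(signal_kernel("poly", 0), "positive")
  expect_error(signal_kernel("exp", -3), "positive")
})

test_that("compute_field sums pairwise kernel values, excluding self", {
  k <- signal_kernel("poly", 2)
  pair <- data.frame(x = c(0L, 1L), y = c(0L, 0L))
  f <- field_values(compute_field(pair, pair, k))
  expect_equal(f$value, c(1, 1))

  line <- data.frame(x = 0:2, y = 0L)
  f <- field_values(compute_field(line, line, k))
  expect_equal(f$value[f$x == 1], 2)       # 1 + 1
  expect_equal(f$value[f$x == 0], 1.25)    # 1 + 1/4
  expect_equal(f$value[f$x == 2], 1.25)

  # corner < edge midpoint < center on a filled square
  sq <- structure_nodes(make_rectangle(5, 5))[c("x", "y")]
  f <- field_values(compute_field(sq, sq, k))
  v <- function(x, y) f$value[f$x == x & f$y == y]
  expect_lt(v(0, 0), v(2, 0))
  expect_lt(v(2, 0), v(2, 2))
  expect_equal(which.max(f$value), which(f$x == 2 & f$y == 2))
  expect_equal(min(f$value), v(0, 0))
})

test_that("compute_field equals the naive double loop on random structures", {
  set.seed(42)
  for (kern in list(signal_kernel("poly", 2), signal_kernel("poly", 0.7),
                    signal_kernel("exp", 1.3))) {
    for (rep in 1:5) {
      n <- sample(5:30, 1)
      g <- expand.grid(x = -4:5, y = -4:5)
      idx <- sample(nrow(g), n)
      src <- g[idx, ]
      ev <- g[sample(nrow(g), 8), ]
      got <- field_values(compute_field(src, ev, kern))$value
      expect_equal(got, naive_field(src, ev, kern), tolerance = 1e-12)
    }
  }
})

test_that("compute_field is monotone and equivariant under lattice symmetries", {
  k <- signal_kernel("poly", 2)
  set.seed(7)
  g <- expand.grid(x = 0:6, y = 0:6)
  src <- g[sample(nrow(g), 12), ]
  ev <- g[sample(nrow(g), 6), ]
  base <- field_values(compute_field(src, ev, k))$value

  # permutation invariance in the source order
  perm <- field_values(compute_field(src[sample(nrow(src)), ], ev, k))$value
  expect_equal(base, perm)

  # adding a source never decreases any value
  more <- field_values(compute_field(rbind(src, data.frame(x = 20, y = 20)),
                                     ev, k))$value
  expect_true(all(more >= base))
  # removing a source never increases any value
  fewer <- field_values(compute_field(src[-1, ], ev, k))$value
  expect_true(all(fewer <= base))

  # translation and 90-degree rotation equivariance
  shift <- function(df) data.frame(x = df$x + 3, y = df$y - 2)
  rot <- function(df) data.frame(x = -df$y, y = df$x)
  expect_equal(field_values(compute_field(shift(src), shift(ev), k))$value, base)
  expect_equal(field_values(compute_field(rot(src), rot(ev), k))$value, base)
})

test_that("old_field and new_field use the documented source sets", {
  k <- signal_kernel("poly", 2)
  s <- amputate(make_rectangle(3, 3), function(x, y) x == 2 & y == 2)
  ctrl <- structure_nodes(s, "control")[c("x", "y")]
  allnodes <- structure_nodes(s)[c("x", "y")]

  old <- old_field(s, k)
  expect_equal(field_values(old)$value, naive_field(allnodes, ctrl, k))

  new <- new_field(s, k)
  expect_equal(field_values(new)$value, naive_field(ctrl, ctrl, k))

  # u* is deterministic under re-amputation with the same mask
  s2 <- amputate(make_rectangle(3, 3), function(x, y) x == 2 & y == 2)
  expect_identical(field_values(old_field(s2, k)), field_values(old))

  # every control value strictly below its remembered value after a cut
  expect_true(all(field_values(new)$value < field_values(old)$value))

  # adding any new cell strictly increases every control cell's signal
  s3 <- s
  s3$nodes <- rbind(s3$nodes, data.frame(x = 5L, y = 5L, role = "new"))
  new3 <- new_field(s3, k)
  expect_true(all(field_values(new3)$value > field_values(new)$value))

  expect_error(old_field(make_rectangle(3, 3), k), "amputated")
})

test_that("deficit_signal is the kernel-weighted deficit sum", {
  k <- signal_kernel("poly", 2)
  ctrl <- data.frame(x = c(0L, 0L), y = c(1L, 2L))
  old <- memregen:::new_signal_field(ctrl$x, ctrl$y, c(5, 4))
  # zero deficit everywhere -> z = 0
  expect_equal(deficit_signal(c(0, 0), old, old, k), 0)

  # deficits (d1, d2) at distances (1, 2): z = d1 + d2/4
  new <- memregen:::new_signal_field(ctrl$x, ctrl$y, c(5 - 0.3, 4 - 0.8))
  expect_equal(deficit_signal(c(0, 0), old, new, k), 0.3 + 0.8 / 4)

  # mismatched node sets are a contract error
  other <- memregen:::new_signal_field(c(1L, 2L), c(0L, 0L), c(1, 1))
  expect_error(deficit_signal(c(0, 0), old, other, k), "different node sets")
  # a candidate on a control node is ill-posed
  expect_error(deficit_signal(c(0, 1), old, new, k), "coincides")
})

test_that("total_signal sums values and is additive over subsets", {
  k <- signal_kernel("poly", 2)
  pair <- data.frame(x = c(0L, 1L), y = c(0L, 0L))
  f <- compute_field(pair, pair, k)
  expect_equal(total_signal(f), 2)

  sq <- structure_nodes(make_rectangle(4, 3))[c("x", "y")]
  f <- compute_field(sq, sq, k)
  fv <- field_values(f)
  part1 <- memregen:::new_signal_field(fv$x[1:5], fv$y[1:5], fv$value[1:5])
  part2 <- memregen:::new_signal_field(fv$x[-(1:5)], fv$y[-(1:5)], fv$value[-(1:5)])
  expect_equal(total_signal(f), total_signal(part1) + total_signal(part2))
})

test_that("fields round-trip exactly through CSV", {
  k <- signal_kernel("poly", 1.7)
  sq <- structure_nodes(make_rectangle(6, 4))[c("x", "y")]
  f <- compute_field(sq, sq, k)
  path <- tempfile(fileext = ".csv")
  write_field_csv(f, path)
  back <- read_field_csv(path)
  expect_identical(field_values(back)$value, field_values(f)$value)
})
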