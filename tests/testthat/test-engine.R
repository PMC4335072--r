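k2 <- signal_kernel("poly", 2)

test_that("candidate_set applies condition 1 but not condition 2", {
  s <- amputate(make_rectangle(6, 4), function(x, y) y >= 3)
  cand <- candidate_set(s, regen_config())
  # the whole removed row is candidate, plus nodes flanking the blastema
  expect_true(all(key(0:5, 3L) %in% key(cand$x, cand$y)))
  # nothing occupied is ever a candidate
  occ <- structure_nodes(s)
  occ <- occ[occ$role != "removed", ]
  expect_false(any(key(cand$x, cand$y) %in% key(occ$x, occ$y)))
  # every candidate is 8-adjacent to a blastema or new cell
  bl <- blastema(s)
  for (i in seq_len(nrow(cand))) {
    expect_true(any(abs(bl$x - cand$x[i]) <= 1 & abs(bl$y - cand$y[i]) <= 1))
  }
  # placing a new cell opens its empty neighbors
  s2 <- s
  s2$nodes <- rbind(s2$nodes, data.frame(x = 2L, y = 3L, role = "new"))
  cand2 <- candidate_set(s2, regen_config())
  expect_true(key(2L, 4L) %in% key(cand2$x, cand2$y))
  expect_false(key(2L, 3L) %in% key(cand2$x, cand2$y))  # now occupied
})

test_that("admissible implements the relative-overshoot filter and its toggle", {
  s <- amputate(make_rectangle(6, 4), function(x, y) y >= 3)
  old <- old_field(s, k2)
  cur <- new_field(s, k2)
  cand <- candidate_set(s, regen_config())
  ok <- admissible(cand, old, cur, k2, 1e-14)
  # early in regeneration, the removed row itself is admissible
  in_row <- key(cand$x, cand$y) %in% key(0:5, 3L)
  expect_true(all(ok[in_row]))
  # with the filter off every candidate passes
  expect_true(all(admissible(cand, old, cur, k2, 1e-14, enforce = FALSE)))
  # a candidate hugging control cells far under their remembered value is
  # rejected once regeneration is essentially complete
  done <- s
  rem <- structure_nodes(s, "removed")
  done$nodes <- rbind(done$nodes[done$nodes$role != "removed", ],
                      data.frame(x = rem$x, y = rem$y, role = "new"))
  curdone <- new_field(done, k2)
  out <- data.frame(x = -1L, y = 1L)
  expect_false(admissible(out, old, curdone, k2, 1e-14))
})

test_that("selection rules return the brute-force argmax with fixed ties", {
  s <- amputate(make_rectangle(6, 4), function(x, y) y >= 3)
  old <- old_field(s, k2)
  cur <- new_field(s, k2)
  single <- data.frame(x = 2L, y = 3L)
  expect_identical(select_3a(single, old, cur, k2), single)
  expect_identical(select_3b(single, old, cur, k2), single)
  expect_null(select_3a(single[0, ], old, cur, k2))

  # two-control-cell textbook case: the position maximizing f(dAC)+f(dBC)
  ab <- cell_structure(c(0L, 2L, 1L), c(0L, 0L, 1L))
  sab <- amputate(ab, data.frame(x = 1L, y = 1L))
  oldab <- old_field(sab, k2)
  curab <- new_field(sab, k2)
  candab <- candidate_set(sab, regen_config())
  expect_gt(nrow(candab), 0L)
  pick <- select_3a(candab, oldab, curab, k2)
  score <- function(x, y) sum(kernel_eval(k2, sqrt((c(0, 2) - x)^2 + y^2)))
  best <- max(mapply(score, candab$x, candab$y))
  expect_equal(score(pick$x, pick$y), best)
})

test_that("detect_violations flags overshoot and ranks the worst cell", {
  ctrl <- data.frame(x = 0:2, y = 0L)
  old <- memregen:::new_signal_field(ctrl$x, ctrl$y, c(2, 2, 2))
  newf <- memregen:::new_signal_field(ctrl$x, ctrl$y, c(2, 2, 2))
  v <- detect_violations(old, newf, 1e-14)
  expect_equal(nrow(v$violations), 0L)
  expect_null(v$worst)

  # one violator is also the worst
  newf$values$value <- c(2, 2.1, 2)
  v <- detect_violations(old, newf, 1e-14)
  expect_equal(nrow(v$violations), 1L)
  expect_equal(v$worst$x, 1L)

  # of two violators, worst has the larger absolute difference
  newf$values$value <- c(2.05, 2.2, 2)
  v <- detect_violations(old, newf, 1e-14)
  expect_equal(nrow(v$violations), 2L)
  expect_equal(v$worst$x, 1L)
})

test_that("a single removed cell is restored in one step", {
  s <- amputate(make_rectangle(4, 4), data.frame(x = 2L, y = 2L))
  for (rule in c("3a", "3b")) {
    r <- regenerate(s, k2, regen_config(rule))
    expect_equal(r$status, "exact")
    expect_equal(r$steps, 1L)
    expect_identical(r$new_nodes, data.frame(x = 2L, y = 2L),
                     ignore_attr = TRUE)
  }
})

test_that("straight-cut rectangle regenerates exactly; condition 2 is necessary", {
  s <- amputate(make_rectangle(12, 8), function(x, y) y >= 6)
  rem <- structure_nodes(s, "removed")
  orig <- original_nodes(s)
  for (rule in c("3a", "3b")) {
    r <- regenerate(s, k2, regen_config(rule))
    expect_equal(r$status, "exact")
    expect_setequal(key(r$new_nodes$x, r$new_nodes$y), key(rem$x, rem$y))

    roff <- regenerate(s, k2, regen_config(rule, enforce_condition2 = FALSE))
    expect_equal(roff$status, "violation")
    outside <- !(key(roff$new_nodes$x, roff$new_nodes$y) %in%
                   key(orig$x, orig$y))
    expect_gt(sum(outside), 0L)
    expect_gt(nrow(roff$violations), 0L)
    expect_false(is.null(roff$worst_violation))
  }
})

test_that("runs are deterministic and traces well-formed", {
  s <- amputate(make_ellipse(5, 3), function(x, y) y >= 2)
  r1 <- regenerate(s, k2, regen_config("3b"))
  r2 <- regenerate(s, k2, regen_config("3b"))
  expect_identical(r1$trace, r2$trace)
  expect_equal(nrow(r1$trace), r1$steps)
  # S(t) strictly increases along the trace
  expect_true(all(diff(r1$trace$S_t) > 0))
  expect_true(r1$trace$S_t[1] > 0)
  # every new cell connects to the blastema through earlier new cells
  grown <- rbind(blastema(s), r1$new_nodes)
  expect_equal(n_components8(grown), 1L)
})

test_that("regenerate validates its input state", {
  expect_error(regenerate(make_rectangle(4, 4), k2), "amputated")
  # step limit is reported as such
  s <- amputate(make_rectangle(12, 8), function(x, y) y >= 6)
  r <- regenerate(s, k2, regen_config("3b", max_steps = 3))
  expect_equal(r$status, "step_limit")
  expect_equal(r$steps, 3L)
})

test_that("organizer growth reuses the engine with a prescribed target", {
  org <- make_rectangle(4, 4, origin = c(1, 1))
  orgn <- structure_nodes(org)[c("x", "y")]
  self <- compute_field(orgn, orgn, k2)

  # target equal to the self-field: nothing to grow
  r0 <- grow_from_organizer(org, self, k2)
  expect_equal(r0$status, "exact")
  expect_equal(r0$steps, 0L)

  # target from an enclosing 6x6: growth reduces to regeneration and
  # reproduces the enclosing shape exactly, under both rules
  big <- make_rectangle(6, 6)
  bign <- structure_nodes(big)[c("x", "y")]
  tgt <- compute_field(bign, orgn, k2)
  for (rule in c("3a", "3b")) {
    r <- grow_from_organizer(org, tgt, k2, regen_config(rule))
    expect_equal(r$status, "exact")
    grown <- c(key(orgn$x, orgn$y), key(r$new_nodes$x, r$new_nodes$y))
    expect_setequal(grown, key(bign$x, bign$y))
  }

  # an asymmetric target (extra mass on both flanks) grows on both sides
  flank <- rbind(bign,
                 expand.grid(x = -3:-1, y = 0:5),
                 expand.grid(x = 6:8, y = 0:5))
  tgt2 <- compute_field(flank, orgn, k2)
  r2 <- grow_from_organizer(org, tgt2, k2, regen_config("3b", max_steps = 400))
  expect_gt(sum(r2$new_nodes$x < 1), 0L)
  expect_gt(sum(r2$new_nodes$x > 4), 0L)

  # an infeasible target (below the self-field) is rejected
  bad <- self
  bad$values$value[3] <- bad$values$value[3] * 0.9
  expect_error(grow_from_organizer(org, bad, k2), "infeasible")
  # a target on the wrong node set is rejected
  wrong <- compute_field(bign, bign, k2)
  expect_error(grow_from_organizer(org, wrong, k2), "exactly on the organizer")
})
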