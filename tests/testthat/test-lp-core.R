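test_that("LP assembly converts prices to cost per 100 g edible portion", {
  b <- tiny_bundle()
  rq <- build_requirement_set("M_19-30", b$dri, "EAR")
  lp <- assemble_lp(b, "AAA", rq)
  # price 20 LCU/kg at edible fraction 0.8 -> 2.5 LCU per 100 g edible
  idx <- match("orange", lp$item_ids)
  pr <- b$prices$price_lcu_per_kg[b$prices$country_id == "AAA" &
                                    b$prices$item_id == "orange"]
  ef <- b$foods$edible_fraction[b$foods$item_id == "orange"]
  expect_equal(lp$cost[idx], pr / (10 * ef))
  # edible fraction 1 -> price/10 exactly
  idx1 <- match("rice", lp$item_ids)
  pr1 <- b$prices$price_lcu_per_kg[b$prices$country_id == "AAA" &
                                     b$prices$item_id == "rice"]
  expect_equal(lp$cost[idx1], pr1 / 10)
  # 1 energy equality + 19 lower + 17 upper rows, one column per priced item
  expect_equal(dim(lp$mat), c(37L, 4L))
  expect_equal(sum(lp$dir == "="), 1L)
  expect_equal(sum(lp$dir == ">="), 19L)
  expect_equal(sum(lp$dir == "<="), 17L)
  # vitamin A rows read different composition columns
  expect_equal(unname(lp$mat["lb:vitamin_a", ]), b$foods$vitamin_a_rae)
  expect_equal(unname(lp$mat["ub:vitamin_a", ]), b$foods$retinol)
  expect_error(assemble_lp(b, "ZZZ", rq), "no priced items")
})

test_that("fixtureA reproduces its closed-form optimum exactly", {
  fx <- analytic_fixture("fixtureA")
  sol <- solve_cona(fx$problem)
  expect_equal(sol$status, "optimal")
  expect_equal(sol$cona_lcu, fx$expected$cona, tolerance = 1e-10)
  expect_equal(sol$quantities, fx$expected$quantities, tolerance = 1e-8)
  expect_equal(sol$duals, fx$expected$duals, tolerance = 1e-10)
  expect_setequal(binding_constraints(sol), fx$expected$binding)
  # binding set is robust to the tolerance on exact-rational data
  expect_setequal(binding_constraints(sol, rel_tol = 0),
                  binding_constraints(sol, rel_tol = 1e-6))
})

test_that("uniform price scaling scales cost and preserves quantities", {
  fx <- analytic_fixture("fixtureA")
  p2 <- fx$problem
  p2$cost <- 2 * p2$cost
  sol2 <- solve_cona(p2)
  expect_equal(sol2$cona_lcu, 2 * fx$expected$cona, tolerance = 1e-10)
  expect_equal(sol2$quantities, fx$expected$quantities, tolerance = 1e-8)
})

test_that("an unsatisfiable nutrient bound yields status infeasible", {
  fx <- analytic_fixture("fixtureA")
  p <- fx$problem
  p$mat <- rbind(p$mat, `lb:calcium` = c(0, 0))
  p$dir <- c(p$dir, ">=")
  p$rhs <- c(p$rhs, 500)
  p$constraint_ids <- c(p$constraint_ids, "lb:calcium")
  sol <- solve_cona(p)
  expect_equal(sol$status, "infeasible")
  expect_null(sol$quantities)
  expect_error(binding_constraints(sol), "optimal")
})

test_that("solver agrees with vertex enumeration on random small diets", {
  set.seed(101)
  n_checked <- 0L
  for (i in 1:220) {
    lp <- random_small_lp()
    a <- lp_solve(lp$obj, lp$mat, lp$dir, lp$rhs)
    b <- lp_enumerate(lp$obj, lp$mat, lp$dir, lp$rhs)
    expect_equal(a$status == "optimal", b$status == "optimal", info = i)
    if (a$status == "optimal") {
      n_checked <- n_checked + 1L
      expect_equal(a$objective, b$objective,
                   tolerance = 1e-8, info = i)
    }
  }
  expect_gte(n_checked, 100L)
})

test_that("solver agrees with the boot simplex on feasible instances", {
  skip_if_not_installed("boot")
  set.seed(202)
  for (i in 1:40) {
    lp <- random_small_lp()
    a <- lp_solve(lp$obj, lp$mat, lp$dir, lp$rhs)
    if (a$status != "optimal") next
    pick <- function(d) {
      if (!any(lp$dir == d)) return(list(A = NULL, b = NULL))
      list(A = lp$mat[lp$dir == d, , drop = FALSE], b = lp$rhs[lp$dir == d])
    }
    # boot::simplex mishandles problems without <= rows; a trivially slack
    # cap keeps the instance equivalent
    n <- length(lp$obj)
    le <- pick("<="); ge <- pick(">="); eq <- pick("=")
    le$A <- rbind(le$A, rep(1, n)); le$b <- c(le$b, 1e8)
    bs <- boot::simplex(a = lp$obj, A1 = le$A, b1 = le$b,
                        A2 = ge$A, b2 = ge$b, A3 = eq$A, b3 = eq$b,
                        maxi = FALSE)
    if (bs$solved == 1) {
      expect_equal(a$objective, unname(bs$value), tolerance = 1e-6,
                   info = i)
    }
  }
})

test_that("tightening any bound never decreases the optimum", {
  set.seed(303)
  fx <- analytic_fixture("fixtureB")
  base <- solve_cona(fx$problem)
  for (i in 1:30) {
    p <- fx$problem
    j <- sample(seq_along(p$rhs), 1)
    if (p$dir[j] == ">=") {
      p$rhs[j] <- p$rhs[j] * runif(1, 1, 1.2)
    } else if (p$dir[j] == "<=") {
      p$rhs[j] <- p$rhs[j] * runif(1, 0.8, 1)
    } else next
    s <- solve_cona(p)
    if (s$status == "optimal") {
      expect_gte(s$cona_lcu, base$cona_lcu - 1e-9)
    }
  }
})

test_that("vertex solutions satisfy complementary slackness and the food count bound", {
  set.seed(404)
  for (i in 1:50) {
    lp <- random_small_lp()
    a <- lp_solve(lp$obj, lp$mat, lp$dir, lp$rhs)
    if (a$status != "optimal") next
    lhs <- as.numeric(lp$mat %*% a$x)
    slack <- abs(lhs - lp$rhs) > 1e-6 * pmax(1, abs(lp$rhs))
    nonbinding <- slack & lp$dir != "="
    expect_true(all(abs(a$duals[nonbinding]) <= 1e-8), info = i)
    n_binding <- sum(!nonbinding)
    expect_lte(sum(a$x > 1e-7), n_binding)
  }
})

test_that("solutions are feasible within tolerance and report grams per day", {
  b <- tiny_bundle()
  rq <- build_requirement_set("F_19-30", b$dri, "EAR")
  sol <- solve_cona(assemble_lp(b, "BBB", rq))
  if (sol$status == "optimal") {
    expect_equal(unname(sol$achieved["energy"]), rq$eer, tolerance = 1e-7)
    lbs <- paste0("lb:", names(rq$lower_bounds))
    expect_true(all(sol$achieved[lbs] >=
                      rq$lower_bounds - 1e-6 * pmax(1, rq$lower_bounds)))
    ubs <- paste0("ub:", names(rq$upper_bounds))
    expect_true(all(sol$achieved[ubs] <=
                      rq$upper_bounds + 1e-6 * pmax(1, rq$upper_bounds)))
    expect_true(all(sol$quantities >= -1e-9))
  } else {
    succeed("tiny 4-food country infeasible for this group")
  }
})
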