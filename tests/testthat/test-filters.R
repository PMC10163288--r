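test_that("default criteria implement strict two-stage thresholds", {
  tab <- data.frame(
    design_id = c("pass", "boundary_pae", "boundary_rmsd", "missing"),
    pae_interaction = c(4.5, 10.0, 7.0, 3.0),
    af2_complex_rmsd = c(1.2, 2.0, 5.0, NA))
  v <- apply_filter(tab, default_criteria())
  expect_equal(v$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(v$failed_criteria[2], "pae_interaction")
  expect_equal(v$failed_criteria[3], "af2_complex_rmsd")
  expect_equal(v$missing_metrics[4], "af2_complex_rmsd")
  # pass is true iff both failure lists are empty
  expect_equal(v$pass, v$failed_criteria == "" & v$missing_metrics == "")
})

test_that("criteria support direction, strictness and schema validation", {
  tab <- data.frame(design_id = c("a", "b"), plddt = c(85, 90))
  keep_high <- filter_criteria(plddt = list(bound = 85, direction = "above",
                                            strict = FALSE))
  expect_equal(apply_filter(tab, keep_high)$pass, c(TRUE, TRUE))
  strict_high <- filter_criteria(plddt = list(bound = 85, direction = "above"))
  expect_equal(apply_filter(tab, strict_high)$pass, c(FALSE, TRUE))
  expect_error(filter_criteria(unknown_metric = 1, schema = c("plddt")),
               "unknown metric")
  expect_error(filter_criteria(), "at least one")
})

test_that("criteria round-trip through YAML config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("pae_interaction: 10",
               "binder_plddt:", "  bound: 80", "  direction: above",
               "  strict: false"), path)
  crit <- criteria_from_yaml(path)
  expect_equal(crit$pae_interaction$bound, 10)
  expect_equal(crit$binder_plddt$direction, "above")
  expect_false(crit$binder_plddt$strict)
})

test_that("pass set shrinks monotonically as thresholds tighten", {
  tab <- random_score_table(200, c("pae_interaction", "af2_complex_rmsd"), 42)
  bounds <- c(15, 10, 7, 4)
  sets <- lapply(bounds, function(b) {
    crit <- filter_criteria(pae_interaction = b, af2_complex_rmsd = 5)
    v <- apply_filter(tab, crit)
    v$design_id[v$pass]
  })
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
})

test_that("pareto_front returns exactly the non-dominated set", {
  single <- data.frame(design_id = "only", x = 1, y = 2)
  expect_equal(pareto_front(single, list(c("x", "min"), c("y", "min"))), "only")
  two <- data.frame(design_id = c("a", "b"), x = c(1, 2), y = c(1, 2))
  expect_equal(pareto_front(two, list(c("x", "min"), c("y", "min"))), "a")
  expect_error(pareto_front(two, list()), "non-empty")
  # direction-aware: maximizing flips domination
  expect_equal(pareto_front(two, list(c("x", "max"), c("y", "max"))), "b")
  # property: output never contains a dominated record
  for (seed in c(3, 14, 15)) {
    tab <- random_score_table(60, c("m1", "m2", "m3"), seed)
    objs <- list(c("m1", "min"), c("m2", "max"), c("m3", "min"))
    expect_setequal(pareto_front(tab, objs), oracle_pareto(tab, objs))
  }
})

test_that("pareto_select peels fronts to an exact quota", {
  tab <- random_score_table(50, c("m1", "m2", "pae_interaction"), 7)
  objs <- list(c("m1", "min"), c("m2", "min"))
  all_ids <- pareto_select(tab, objs, quota = 50)
  expect_setequal(all_ids, tab$design_id)
  front1 <- pareto_front(tab, objs)
  expect_setequal(pareto_select(tab, objs, quota = length(front1)), front1)
  expect_equal(all_ids[seq_along(front1)][order(all_ids[seq_along(front1)])],
               sort(front1))
  # peeling oracle: selection is the union of leading fronts plus a
  # tie-break-ordered prefix of the next
  quota <- length(front1) + 3
  sel <- pareto_select(tab, objs, quota)
  expect_equal(length(sel), quota)
  expect_true(all(front1 %in% sel))
  rest <- tab[!tab$design_id %in% front1, ]
  front2 <- pareto_front(rest, objs)
  extra <- setdiff(sel, front1)
  f2 <- rest[rest$design_id %in% front2, ]
  expected_extra <- f2$design_id[order(f2$pae_interaction, f2$design_id)][1:3]
  expect_equal(sort(extra), sort(expected_extra))
  expect_error(pareto_select(tab, objs, 0), "positive")
  expect_error(pareto_select(tab, objs, 51), "exceeds")
})

test_that("select_top_fraction picks ceiling(fraction*n) best with stable ties", {
  tab <- data.frame(design_id = sprintf("d%02d", 1:10),
                    m = c(5, 3, 8, 1, 9, 2, 7, 4, 6, 10))
  expect_setequal(select_top_fraction(tab, "m", 1.0), tab$design_id)
  expect_equal(select_top_fraction(tab, "m", 0.2, "min"), c("d04", "d06"))
  expect_equal(select_top_fraction(tab, "m", 0.2, "max"), c("d10", "d05"))
  # ties broken lexicographically by design_id
  ties <- data.frame(design_id = c("z", "a", "m"), m = c(1, 1, 1))
  expect_equal(select_top_fraction(ties, "m", 2 / 3), c("a", "m"))
  expect_error(select_top_fraction(tab, "absent", 0.5), "present")
  expect_error(select_top_fraction(tab, "m", 0), "fraction")
  # size property against a sort-based oracle
  for (seed in c(2, 9)) {
    rt <- random_score_table(37, "m", seed)
    for (f in c(0.01, 0.1, 0.5, 0.99)) {
      sel <- select_top_fraction(rt, "m", f, "min")
      expect_equal(length(sel), ceiling(f * 37))
      oracle <- rt$design_id[order(rt$m, rt$design_id)][seq_len(ceiling(f * 37))]
      expect_equal(sel, oracle)
    }
  }
})
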