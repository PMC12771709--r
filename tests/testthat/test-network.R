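toy_graph <- function() {
  signed_graph(data.frame(from = c("A", "A", "B"), to = c("B", "C", "D"),
                          sign = c(1, -1, 1)))
}

test_that("signed graphs validate edges and parse word signs", {
  g <- signed_graph(data.frame(from = "X", to = "Y", sign = "inhibits"))
  expect_equal(g$edges$sign, -1)
  expect_error(signed_graph(data.frame(from = c("X", "X"), to = c("Y", "Y"),
                                       sign = c(1, -1))), "Conflicting")
  expect_error(signed_graph(data.frame(from = "X", to = "Y", sign = 2)), "sign")
  # exact duplicates collapse
  g2 <- signed_graph(data.frame(from = c("X", "X"), to = c("Y", "Y"),
                                sign = c(1, 1)))
  expect_equal(nrow(g2$edges), 1L)
})

test_that("edge lists round-trip through TSV including the SIF dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t+1", "A\tC\t-1", "B\tD\t1"), path)
  g <- read_signed_graph(path)
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$sign, c(1, -1, 1))
  writeLines(c("A\tactivates\tB", "A\tinhibits\tC"), path)
  sif <- read_signed_graph(path)
  expect_equal(sif$edges$to, c("B", "C"))
  expect_equal(sif$edges$sign, c(1, -1))
})

test_that("sign propagation follows path-sign products", {
  g <- toy_graph()
  down <- propagate_sign(g, "A", "down")
  expect_equal(setNames(down$predicted, down$node),
               c(B = -1, C = 1, D = -1))
  up <- propagate_sign(g, "A", "up")
  expect_equal(setNames(up$predicted, up$node), c(B = 1, C = -1, D = 1))
  # isolated source
  iso <- signed_graph(data.frame(from = "A", to = "B", sign = 1), nodes = "Z")
  expect_equal(nrow(propagate_sign(iso, "Z", "down")), 0L)
  expect_error(propagate_sign(g, "NOPE", "down"), "NOPE")
})

test_that("agreeing multi-path products stay unambiguous, conflicts become ambiguous", {
  # A -(+)-> B and A -(-)-> X -(-)-> B: both paths give +1
  agree <- signed_graph(data.frame(from = c("A", "A", "X"), to = c("B", "X", "B"),
                                   sign = c(1, -1, -1)))
  res <- propagate_sign(agree, "A", "down")
  expect_false(res$ambiguous[res$node == "B"])
  expect_equal(res$predicted[res$node == "B"], -1)

  conflict <- signed_graph(data.frame(from = c("A", "A", "X"), to = c("B", "X", "B"),
                                      sign = c(1, -1, 1)))
  res2 <- propagate_sign(conflict, "A", "down")
  expect_true(res2$ambiguous[res2$node == "B"])
  expect_true(is.na(res2$predicted[res2$node == "B"]))
})

test_that("perturbagen scoring reverts observed signs as in the worked example", {
  g <- toy_graph()
  obs <- c(B = 1, C = 1, D = 1)
  ranks <- perturbagen_score(g, obs)
  a <- ranks[ranks$node == "A", ]
  expect_equal(a$score, 2L)            # down reverts B and D, C stays +1
  expect_equal(a$direction, "down")
  expect_setequal(a$reverted[[1]], c("B", "D"))
  expect_equal(ranks$score[ranks$node == "D"], 0L)  # no out-edges
  expect_error(perturbagen_score(g, c()), "observed")
  expect_error(perturbagen_score(g, c(B = 2)), "\\+1/-1")
})

test_that("negating all observed signs leaves scores invariant", {
  set.seed(3)
  g <- random_signed_graph(7, 0.3, seed = 12)
  obs <- setNames(sample(c(-1, 1), 7, replace = TRUE), LETTERS[1:7])
  s1 <- perturbagen_score(g, obs)
  s2 <- perturbagen_score(g, -obs)
  expect_equal(setNames(s1$score, s1$node), setNames(s2$score, s2$node))
})

test_that("scores equal the exhaustive simple-path oracle on random graphs", {
  for (seed in 1:30) {
    n <- sample(4:8, 1)
    g <- random_signed_graph(n, 0.35, seed = 100 + seed)
    set.seed(200 + seed)
    obs <- setNames(sample(c(-1, 1), n, replace = TRUE), LETTERS[seq_len(n)])
    got <- perturbagen_score(g, obs)
    want <- oracle_perturbagen(g, obs)
    expect_equal(setNames(got$score, got$node)[want$node],
                 setNames(want$score, want$node))
    expect_true(all(got$score >= 0 & got$score <= length(obs)))
  }
})

test_that("topology roles: betweenness, hubs and attractors", {
  path <- signed_graph(data.frame(from = c("A", "B"), to = c("B", "C"), sign = 1))
  roles <- topology_roles(path, hub_quantile = 0.9)
  # one of two feasible ordered pairs routes through B: 1 / ((n-1)(n-2)) = 0.5
  expect_equal(roles$betweenness[roles$node == "B"], 0.5)
  expect_equal(roles$betweenness[roles$node %in% c("A", "C")], c(0, 0))
  expect_identical(roles$node[roles$attractor], "A")
  expect_true(roles$hub[roles$node == "B"])

  # complete directed graph: every pair is directly connected
  cg <- expand.grid(from = LETTERS[1:4], to = LETTERS[1:4],
                    stringsAsFactors = FALSE)
  cg <- cg[cg$from != cg$to, ]; cg$sign <- 1
  r2 <- topology_roles(signed_graph(cg))
  expect_true(all(r2$betweenness == 0))
  expect_false(any(r2$attractor))
})
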