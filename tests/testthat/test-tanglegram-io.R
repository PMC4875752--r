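MINIMAL_NEXUS <- paste(
  "#NEXUS",
  "BEGIN TREES;",
  "TREE HOST = ((a,b)x,c)r;",
  "TREE PARASITE = ((A,B)y,C)z;",
  "END;",
  "BEGIN ASSOCIATIONS;",
  "A : a, B : b, C : c;",
  "END;",
  sep = "\n")

test_that("the minimal NEXUS dialect parses", {
  tg <- read_tanglegram(text = MINIMAL_NEXUS)
  expect_equal(n_tips(tg$host), 3L)
  expect_equal(n_tips(tg$parasite), 3L)
  expect_equal(nrow(tg$associations), 3L)
  expect_true(validate_dating(tg$host))   # canonical dating applied
})

test_that("a DATING block overrides the canonical dating", {
  nex <- paste(
    "#NEXUS",
    "BEGIN TREES;",
    "TREE HOST = ((a,b)x,(c,d)y)r;",
    "TREE PARASITE = ((A,B)u,(C,D)v)w;",
    "END;",
    "BEGIN ASSOCIATIONS;",
    "A : a, B : b, C : c, D : d;",
    "END;",
    "BEGIN DATING;",
    "r = 1; y = 2; x = 3;",
    "END;", sep = "\n")
  tg <- read_tanglegram(text = nex)
  expect_true(validate_dating(tg$host))
  expect_equal(node_rank(tg$host)[resolve_node(tg$host, "y")], 2L)
  expect_equal(node_rank(tg$host)[resolve_node(tg$host, "x")], 3L)
  # child predating its parent is rejected
  expect_error(read_tanglegram(text = sub("r = 1; y = 2; x = 3;",
                                          "r = 2; y = 1; x = 3;", nex)),
               "predate")
})

test_that("the single-host constraint is enforced", {
  bad <- sub("A : a, B : b, C : c;", "A : a, A : b, C : c;", MINIMAL_NEXUS)
  expect_error(read_tanglegram(text = bad), "exactly one host")
  unknown <- sub("A : a", "A : zz", MINIMAL_NEXUS)
  expect_error(read_tanglegram(text = unknown), "zz")
  # many parasite leaves on one host leaf is allowed
  many <- sub("A : a, B : b, C : c;", "A : a, B : a, C : a;", MINIMAL_NEXUS)
  expect_equal(unique(read_tanglegram(text = many)$associations$host), "a")
})

test_that("write -> read round trips and is byte-stable", {
  set.seed(51)
  for (k in 1:100) {
    tg <- sim_tanglegram(sample(2:25, 1), if (k %% 2) "yule" else "uniform",
                         fan_out = k %% 3 == 0)
    txt <- write_tanglegram(tg)
    back <- read_tanglegram(text = txt)
    expect_true(tanglegrams_equal(tg, back))
    expect_identical(write_tanglegram(back), txt)   # fixed point
  }
})

test_that("NEXUS output carries one DATING entry per host internal node", {
  tg <- sim_tanglegram(9, "uniform", seed = 3)
  txt <- write_tanglegram(tg)
  dating <- regmatches(txt, regexpr("(?s)BEGIN DATING;.*?END;", txt,
                                    perl = TRUE))
  expect_equal(lengths(regmatches(dating, gregexpr("=", dating))), 8L)
})

test_that("newick + TSV input reads the same tanglegram", {
  tg <- sim_tanglegram(7, "yule", seed = 9)
  prefix <- file.path(withr::local_tempdir(), "tg")
  write_tanglegram(tg, file = prefix, format = "newick+tsv")
  back <- read_tanglegram(host = paste0(prefix, ".host.nwk"),
                          parasite = paste0(prefix, ".parasite.nwk"),
                          assoc = paste0(prefix, ".tsv"))
  expect_true(trees_isomorphic(tg$host, back$host))
  expect_true(trees_isomorphic(tg$parasite, back$parasite))
  expect_equal(as.data.frame(back$associations[
    order(back$associations$parasite), ]),
    as.data.frame(tg$associations[order(tg$associations$parasite), ]))
})
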