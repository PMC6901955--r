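fixture <- function(name) system.file("extdata", name, package = "immunorules")

test_that("rules serialize in the IF-THEN dialect with <= and >= operators", {
  rs <- rule_set(list(new_rule("CSGAGFEGTGLRCSLLCLDR", "<=", 0.795,
                               "Esophageal cancer")),
                 default_class = "Breast cancer")
  tmp <- withr::local_tempfile()
  write_rules(rs, tmp)
  lines <- readLines(tmp)
  expect_equal(lines[1],
               "IF CSGAGFEGTGLRCSLLCLDR<=0.795 THEN type = \"Esophageal cancer\"")
  expect_equal(lines[2], "IF Others THEN type = \"Breast cancer\"")
})

test_that("an empty rule set serializes to a single default line", {
  tmp <- withr::local_tempfile()
  write_rules(rule_set(list(), "Healthy control"), tmp)
  expect_equal(readLines(tmp), "IF Others THEN type = \"Healthy control\"")
  expect_equal(read_rules(tmp)$default_class, "Healthy control")
})

test_that("malformed rule files are rejected with the line number", {
  tmp <- withr::local_tempfile()
  writeLines(c("IF A<=1 THEN type = \"x\"", "not a rule",
               "IF Others THEN type = \"y\""), tmp)
  expect_error(read_rules(tmp), "line 2")
  writeLines(c("IF A<=1 THEN type = \"x\""), tmp)
  expect_error(read_rules(tmp), "default")
})

test_that("the published 7-rule set round-trips and applies first-match", {
  rs <- read_rules(fixture("rules_dataset1.txt"))
  expect_length(rs$rules, 6L)
  expect_equal(rs$default_class, "Breast cancer")
  tmp <- withr::local_tempfile()
  write_rules(rs, tmp)
  expect_identical(read_rules(tmp), rs)

  feats <- unique(unlist(lapply(rs$rules, function(r) r$conditions$feature)))
  probe <- stats::setNames(rep(1.0, length(feats)), feats)
  probe["CSGAGFEGTGLRCSLLCLDR"] <- 0.5
  expect_equal(apply_rules(rs, probe), "Esophageal cancer")

  # violates at least one condition of every rule 1..6 -> default class
  # (rule 2 fails via its first peptide, rule 6 via the 1.282 bound)
  none <- c(CSGAGFEGTGLRCSLLCLDR = 1.0, CSGFQPMRYPFQDPYHGYGW = 2.0,
            CSGADFVTYATRRVQFMMHK = 1.2, CSGFLMEHQNLLERSEDAKA = 1.0,
            CSGGEGIQATYHKVGGNFLG = 0.5, CSGTYEPHLVYLATFTDGIP = 1.0,
            CSGEKIGMEQHYNQWIELMR = 0.5)
  expect_equal(apply_rules(rs, none), "Breast cancer")

  # ordered first-match: a sample satisfying rule 1 and rule 6 takes rule 1
  both <- none
  both["CSGAGFEGTGLRCSLLCLDR"] <- 0.5          # rule 1 fires
  both["CSGADFVTYATRRVQFMMHK"] <- 2.0          # rule 6 would fire too
  expect_equal(apply_rules(rs, both), "Esophageal cancer")

  expect_error(apply_rules(rs, none[-1]), "lacks feature")
})

test_that("the published 42-rule set parses with its duplicated rule intact", {
  rs <- read_rules(fixture("rules_dataset2.txt"))
  expect_length(rs$rules, 41L)
  expect_equal(rs$default_class, "Healthy normal donor")
  expect_identical(rs$rules[[8]], rs$rules[[9]])    # printed twice verbatim
  tmp <- withr::local_tempfile()
  write_rules(rs, tmp)
  expect_identical(read_rules(tmp), rs)

  none <- all_false_probe(rs)
  expect_false(is.null(none))
  expect_equal(apply_rules(rs, none), "Healthy normal donor")
  sarcoma <- none
  sarcoma["HQKNDSANTVITTWLTRGSC"] <- 6.0
  expect_equal(apply_rules(rs, sarcoma), "Sarcoma")
})
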