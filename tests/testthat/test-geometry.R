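supported_templates <- list(
  list("A", "WC", "U", "WC", "cis"), list("U", "WC", "A", "WC", "cis"),
  list("G", "WC", "C", "WC", "cis"), list("C", "WC", "G", "WC", "cis"),
  list("G", "WC", "U", "WC", "cis"), list("U", "WC", "G", "WC", "cis"),
  list("A", "WC", "U", "WC", "trans"), list("G", "WC", "C", "WC", "trans"),
  list("A", "WC", "A", "WC", "trans"),
  list("U", "WC", "A", "Hoogsteen", "trans"),
  list("A", "WC", "A", "Hoogsteen", "trans")
)

test_that("classification round-trips every supported pair template", {
  for (tp in supported_templates) {
    pr <- do.call(build_ideal_pair, tp)
    lw <- classify_lw(pr$r5, pr$r3)
    expect_true(lw$paired, info = paste(unlist(tp), collapse = " "))
    expect_equal(lw$edge5, tp[[2]], info = paste(unlist(tp), collapse = " "))
    expect_equal(lw$edge3, tp[[4]], info = paste(unlist(tp), collapse = " "))
    expect_equal(lw$orientation, tp[[5]],
                 info = paste(unlist(tp), collapse = " "))
    # classified pairs carry H-bonds inside the allowed window
    expect_gt(nrow(lw$hbonds), 0L)
    expect_true(all(lw$hbonds$distance >= 2.4 & lw$hbonds$distance <= 3.5))
    expect_gt(lw$c1_c1, 0)
  }
})

test_that("built H-bonds close at the 2.9 A target", {
  pr <- build_ideal_pair("U", "WC", "A", "Hoogsteen", "trans")
  lw <- classify_lw(pr$r5, pr$r3)
  expect_true(all(abs(lw$hbonds$distance - 2.9) <= 0.05))
  # coplanar construction
  expect_true(all(abs(pr$r5$atoms[, "z"]) < 1e-6))
  expect_true(all(abs(pr$r3$atoms[, "z"]) < 1e-6))
})

test_that("unsupported pair requests raise the template error", {
  expect_error(build_ideal_pair("C", "Sugar", "C", "Sugar", "cis"),
               class = "trnaclover_geometry_error")
})

test_that("cis WC/WC pairs sit in the canonical helix C1'-C1' band", {
  for (tp in supported_templates) {
    if (tp[[5]] != "cis") next
    pr <- do.call(build_ideal_pair, tp)
    d <- c1_distance(pr$r5, pr$r3)
    expect_gt(d, 10.2); expect_lt(d, 10.8)
  }
})

test_that("the wobble U is displaced toward the major groove", {
  gc <- build_ideal_pair("G", "WC", "C", "WC", "cis")
  gu <- build_ideal_pair("G", "WC", "U", "WC", "cis")
  # G is identical (fixed frame); compare the pyrimidine glycosidic N
  shift <- gu$r3$atoms["N1", ] - gc$r3$atoms["N1", ]
  expect_gt(sqrt(sum(shift^2)), 1.2)
  # major-groove side of the G face is where O6 points
  major <- gc$r5$atoms["O6", ] - gc$r5$atoms["N1", ]
  expect_gt(sum(shift * major), 0)
})

test_that("C1' distances are symmetric, rigid-motion invariant, zero at identity", {
  pr <- build_ideal_pair("A", "WC", "U", "WC", "cis")
  expect_equal(c1_distance(pr$r5, pr$r3), c1_distance(pr$r3, pr$r5))
  expect_equal(c1_distance(pr$r5, pr$r5), 0)
  set.seed(5)
  for (k in 1:5) {
    th <- runif(3, 0, 2 * pi)
    Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                   0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
    Rz <- matrix(c(cos(th[2]), -sin(th[2]), 0, sin(th[2]), cos(th[2]), 0,
                   0, 0, 1), 3, 3, byrow = TRUE)
    tr <- runif(3, -20, 20)
    move <- function(r) {
      r$atoms <- r$atoms %*% (Rx %*% Rz) +
        matrix(tr, nrow(r$atoms), 3, byrow = TRUE)
      r
    }
    expect_equal(c1_distance(move(pr$r5), move(pr$r3)),
                 c1_distance(pr$r5, pr$r3))
    lw <- classify_lw(move(pr$r5), move(pr$r3))
    expect_equal(lw$orientation, "cis")
    expect_equal(c(lw$edge5, lw$edge3), c("WC", "WC"))
  }
})

test_that("residues far apart are reported unpaired, not an error", {
  r5 <- standard_base("A")
  r3 <- standard_base("U")
  r3$atoms[, "x"] <- r3$atoms[, "x"] + 30
  lw <- classify_lw(r5, r3)
  expect_false(lw$paired)
  expect_true(is.na(lw$edge5))
  expect_equal(nrow(lw$hbonds), 0L)
})

test_that("standard base geometries satisfy the bonded-distance sanity check", {
  for (b in c("A", "C", "G", "U")) {
    r <- standard_base(b)
    expect_silent(trnaclover:::validate_residue(r))
  }
  broken <- standard_base("G")
  broken$atoms["N1", ] <- broken$atoms["N1", ] + c(3, 0, 0)
  expect_error(trnaclover:::validate_residue(broken),
               class = "trnaclover_geometry_error")
})

test_that("PDB fixtures round-trip through read_pdb_residues", {
  pr <- build_ideal_pair("U", "WC", "A", "Hoogsteen", "trans")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_residues(list(pr$r5, pr$r3), f, resno = c(54, 58))
  res <- read_pdb_residues(f, "A", c(54, 58))
  expect_equal(res[[1]]$base_type, "U")
  expect_equal(res[[2]]$base_type, "A")
  lw <- classify_lw(res[[1]], res[[2]])
  expect_equal(lw$orientation, "trans")
  expect_equal(c(lw$edge5, lw$edge3), c("WC", "Hoogsteen"))
  expect_equal(lw$c1_c1, c1_distance(pr$r5, pr$r3), tolerance = 1e-3)
  # absent residues are an error
  expect_error(read_pdb_residues(f, "A", 99),
               class = "trnaclover_geometry_error")
})

test_that("modified residue names map to parent bases; missing atoms are named", {
  # synthetic T-loop fixture: 5MU (ribothymidine) and 1MA (1-methyladenosine)
  pr <- build_ideal_pair("U", "WC", "A", "Hoogsteen", "trans")
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_residues(list(pr$r5, pr$r3), f, resno = c(54, 58),
                     resid = c("5MU", "1MA"))
  res <- read_pdb_residues(f, "A", c(54, 58))
  expect_equal(res[[1]]$base_type, "U")
  expect_equal(res[[2]]$base_type, "A")
  lw <- classify_lw(res[[1]], res[[2]])
  expect_equal(c(lw$edge5, lw$edge3, lw$orientation),
               c("WC", "Hoogsteen", "trans"))
  # an unknown residue name is an error
  write_pdb_residues(list(pr$r5), f, resno = 54, resid = "ZZZ")
  expect_error(read_pdb_residues(f, "A", 54), "unknown residue")
  # drop the C1' of a residue: the error names the atom
  lines <- readLines(write_pdb_residues(list(pr$r5, pr$r3), f,
                                        resno = c(54, 58)))
  writeLines(lines[!grepl("C1'", lines) | grepl(" 54 ", lines)], f)
  err <- expect_error(read_pdb_residues(f, "A", c(54, 58)),
                      class = "trnaclover_geometry_error")
  expect_match(conditionMessage(err), "C1'")
})
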