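test_that("parse_pdb partitions chains, maps modified residues, honors models", {
  s <- parse_toy()
  expect_s3_class(s, "ptb_structure")
  expect_equal(nrow(peptide_residues(s)), 4)
  expect_equal(sum(s$atoms$role == "domain"), 2)
  expect_equal(peptide_sequence(s), "NPTY")

  # phosphotyrosine alias and water exclusion
  df <- toy_atoms()
  df$resid[6] <- "PTR"
  df <- rbind(df, tibble::tibble(chain = "A", resno = 9L, resid = "HOH",
                                 name = "O", x = 1, y = 1, z = 1,
                                 element = "O"))
  s2 <- parse_toy(df)
  expect_equal(peptide_sequence(s2), "NPTy")
  expect_false(any(s2$atoms$resid == "HOH"))

  # requesting an absent chain is a named-chain error
  path <- withr::local_tempfile(fileext = ".pdb")
  write_toy_pdb(toy_atoms(), path)
  expect_error(parse_pdb(path, domain_chains = "C", peptide_chain = "B"),
               class = "ptb_error_chain")

  # multi-model: model 2 coordinates only (oracle: the numbers written to
  # the MODEL 2 block)
  m1 <- toy_atoms()
  m2 <- dplyr::mutate(m1, x = x + 100)
  write_toy_pdb(NULL, path, models = list(m1, m2))
  s_m2 <- parse_pdb(path, "A", "B", model = 2)
  expect_equal(sort(s_m2$atoms$x), sort(m2$x))
  s_m1 <- parse_pdb(path, "A", "B", model = 1)
  expect_equal(sort(s_m1$atoms$x), sort(m1$x))
  expect_error(parse_pdb(path, "A", "B", model = 3),
               class = "ptb_error_contract")
})

test_that("malformed coordinate records are reported with a line number", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- readLines(write_toy_pdb(toy_atoms(), path))
  substr(lines[3], 31, 38) <- "   xx.yy"
  writeLines(lines, path)
  expect_error(parse_pdb(path, "A", "B"), "line 3",
               class = "ptb_error_parse")
})

test_that("compute_contacts applies a strict any-atom distance criterion", {
  # closest atoms 10 A apart: no contact at 4.5
  df <- toy_atoms()
  df$x <- c(0, 50, 10, 60, 70, 80)
  ct <- compute_contacts(parse_toy(df), 4.5)
  expect_equal(nrow(ct), 0)

  # one CB-CG pair at 4.4 A, everything else > 5 A
  df2 <- tibble::tibble(
    chain = c("A", "A", "A", "B", "B", "B", "B", "B"),
    resno = c(1L, 1L, 2L, 1L, 1L, 2L, 3L, 4L),
    resid = c("LEU", "LEU", "VAL", "ASN", "ASN", "PRO", "THR", "TYR"),
    name = c("CA", "CG", "CA", "CA", "CB", "CA", "CA", "CA"),
    x = c(0, 2, 30, 12.4, 6.4, 20, 26, 40),
    y = c(0, 0, 20, 0, 0, 15, 32, 40),
    z = 0,
    element = c("C", "C", "C", "C", "C", "C", "C", "C")
  )
  s2 <- parse_toy(df2)
  ct2 <- compute_contacts(s2, 4.5)
  expect_equal(nrow(ct2), 1)
  expect_equal(ct2$pep_resno, 1)
  expect_equal(ct2$dom_resno, 1)
  expect_equal(ct2$min_dist, 4.4, tolerance = 1e-6)
  # the same fixture at 4.3 is empty, and 4.4 itself is excluded (strict <)
  expect_equal(nrow(compute_contacts(s2, 4.3)), 0)
  expect_equal(nrow(compute_contacts(s2, 4.4)), 0)
})

test_that("contacts match an exhaustive atom-pair scan and are monotone in cutoff", {
  for (seed in 1:8) {
    s <- random_toy_structure(seed)
    for (cutoff in c(3, 4.5, 6)) {
      ct <- compute_contacts(s, cutoff)
      keys <- paste(ct$pep_chain, ct$pep_resno, "|", ct$dom_chain,
                    ct$dom_resno)
      oracle <- brute_force_contacts(s, cutoff)
      expect_setequal(keys, names(oracle))
      expect_equal(ct$min_dist[order(keys)],
                   unlist(oracle)[sort(keys)], ignore_attr = TRUE)
    }
    # cutoff monotonicity: pairs(c1) subset of pairs(c2) for c1 <= c2
    k1 <- with(compute_contacts(s, 3.5), paste(pep_resno, dom_resno))
    k2 <- with(compute_contacts(s, 5), paste(pep_resno, dom_resno))
    expect_true(all(k1 %in% k2))
  }
})

test_that("pockets re-index peptide residues with the motif Y at zero", {
  ct <- compute_contacts(parse_toy(), 4.5) # NPTY peptide, Y is residue 4
  pk <- build_pockets(ct)
  expect_equal(pk$positions$position, c(-3, -2, -1, 0))
  expect_equal(pk$positions$aa[pk$positions$position == 0], "Y")

  # explicit anchor, and empty contact map -> all-empty pockets
  df <- toy_atoms()
  df$x <- c(0, 50, 100, 160, 170, 180)
  ct0 <- compute_contacts(parse_toy(df), 4.5)
  pk0 <- build_pockets(ct0, y_position = 4)
  expect_equal(nrow(pk0$contacts), 0)
  expect_equal(nrow(pk0$positions), 4)
  expect_error(build_pockets(ct0, y_position = 9),
               class = "ptb_error_contract")

  # union of pocket members equals the domain side of the contact map
  cx_path <- withr::local_tempfile(fileext = ".pdb")
  groove_complex(cx_path)
  ct2 <- compute_contacts(parse_pdb(cx_path, "A", "B"))
  pk2 <- build_pockets(ct2)
  expect_setequal(paste(pk2$contacts$dom_chain, pk2$contacts$dom_resno),
                  paste(ct2$dom_chain, ct2$dom_resno))
})

test_that("hydrogen bonds are N donor / O acceptor pairs within the cutoff", {
  # one domain N at 2.9 A from a peptide O; an intra-residue N-O at 1.3 A
  df <- tibble::tibble(
    chain = c("A", "B", "B", "B", "B", "B"),
    resno = c(1L, 1L, 1L, 2L, 3L, 4L),
    resid = c("LEU", "ASN", "ASN", "PRO", "THR", "TYR"),
    name = c("N", "O", "N", "CA", "CA", "CA"),
    x = c(0, 2.9, 3.5, 20, 30, 40),
    y = 0, z = 0,
    element = c("N", "O", "N", "C", "C", "C")
  )
  s <- parse_toy(df)
  hb <- detect_hbonds(s, 3.5)
  expect_equal(nrow(hb), 1)
  expect_equal(hb$distance, 2.9, tolerance = 1e-6)
  expect_equal(hb$category, "domain-peptide")
  expect_equal(hb$donor_atom, "N")
  expect_equal(hb$acceptor_atom, "O")
  # below the observed distance: empty
  expect_equal(nrow(detect_hbonds(s, 2.5)), 0)
})

test_that("hydrogen bond detection matches a brute-force N/O scan", {
  for (seed in 21:26) {
    s <- random_toy_structure(seed)
    hb <- detect_hbonds(s, 3.4)
    at <- s$atoms
    don <- at[at$elesy == "N", ]
    acc <- at[at$elesy == "O", ]
    n_expected <- 0
    if (nrow(don) > 0 && nrow(acc) > 0) {
      for (i in seq_len(nrow(don))) {
        for (j in seq_len(nrow(acc))) {
          same_res <- don$chain[i] == acc$chain[j] &&
            don$resno[i] == acc$resno[j]
          has_pep <- don$role[i] == "peptide" || acc$role[j] == "peptide"
          d <- sqrt((don$x[i] - acc$x[j])^2 + (don$y[i] - acc$y[j])^2 +
                      (don$z[i] - acc$z[j])^2)
          if (!same_res && has_pep && d <= 3.4) n_expected <- n_expected + 1
        }
      }
    }
    expect_equal(nrow(hb), n_expected)
    expect_false(is.unsorted(hb$distance))
  }
})

test_that("superposition RMSD is zero under rigid motion and matches a quaternion oracle", {
  set.seed(99)
  a <- matrix(rnorm(30), ncol = 3)
  expect_equal(superpose_rmsd(a, a, fit = FALSE), 0)
  expect_equal(superpose_rmsd(a, a), 0)

  # proper rigid transforms of either input leave fitted RMSD at zero
  rot <- function(ax, th) {
    u <- ax / sqrt(sum(ax^2))
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
  }
  for (i in 1:5) {
    b <- a %*% rot(rnorm(3), runif(1, 0, 2 * pi)) +
      matrix(rnorm(3, sd = 10), nrow(a), 3, byrow = TRUE)
    expect_lt(superpose_rmsd(a, b), 1e-8)
    expect_lt(superpose_rmsd(b, a), 1e-8)
  }

  # 4-point toys: value agrees with numerical minimization over rotations
  # parameterized by unit quaternions
  quat_oracle <- function(p, q) {
    p <- sweep(p, 2, colMeans(p)); q <- sweep(q, 2, colMeans(q))
    rmsd_of <- function(v) {
      v <- v / sqrt(sum(v^2))
      w <- v[1]; x <- v[2]; y <- v[3]; z <- v[4]
      R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
                    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
                    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
                  3, 3)
      sqrt(mean(rowSums((q %*% R - p)^2)))
    }
    best <- Inf
    for (k in 1:40) {
      r <- optim(rnorm(4), rmsd_of, method = "BFGS")
      best <- min(best, r$value)
    }
    best
  }
  for (seed in 1:4) {
    set.seed(seed)
    p <- matrix(rnorm(12), 4, 3)
    q <- matrix(rnorm(12), 4, 3)
    expect_equal(superpose_rmsd(p, q), quat_oracle(p, q), tolerance = 1e-6)
  }

  # fit=FALSE on pre-aligned coordinates equals plain RMSD
  d <- a + 0.5
  expect_equal(superpose_rmsd(a, d, fit = FALSE),
               sqrt(mean(rowSums((a - d)^2))))
  expect_error(superpose_rmsd(a, a[1:3, ]), class = "ptb_error_contract")
})
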