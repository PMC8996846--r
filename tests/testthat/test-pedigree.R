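test_that("pedigree validation flags constructed violations", {
  founders <- data.frame(animal_id = c("A", "B", "C"),
                         sire_id = "0", dam_id = "0")
  expect_equal(nrow(validate_pedigree(founders)), 0L)

  self_sire <- data.frame(animal_id = "A", sire_id = "A", dam_id = "0")
  rep1 <- validate_pedigree(self_sire)
  expect_true("cycle" %in% rep1$rule)

  # two-step cycle: A -> B -> A
  cyc <- data.frame(animal_id = c("A", "B"), sire_id = c("B", "A"),
                    dam_id = c("0", "0"))
  expect_true("cycle" %in% validate_pedigree(cyc)$rule)

  dated <- data.frame(animal_id = c("S", "O"), sire_id = c("0", "S"),
                      dam_id = c("0", "0"),
                      birth_date = as.Date(c("2015-01-01", "2010-01-01")))
  expect_true("date_conflict" %in% validate_pedigree(dated)$rule)

  sexed <- data.frame(animal_id = c("S", "O"), sire_id = c("0", "S"),
                      dam_id = c("0", "0"), sex = c("F", "F"))
  expect_true("sex_conflict" %in% validate_pedigree(sexed)$rule)

  dangling <- data.frame(animal_id = "O", sire_id = "GHOST", dam_id = "0")
  expect_true("dangling_parent" %in% validate_pedigree(dangling)$rule)

  expect_error(validate_pedigree(data.frame(animal_id = c("A", "A"),
                                            sire_id = "0", dam_id = "0")),
               "duplicated")
})

test_that("pedigree completeness follows the harmonic-mean definition", {
  # fully known two-generation parental pedigrees -> IPC 1 at depth 1
  ped <- data.frame(
    animal_id = c("gs1", "gd1", "gs2", "gd2", "S", "D", "X"),
    sire_id  = c("0", "0", "0", "0", "gs1", "gs2", "S"),
    dam_id   = c("0", "0", "0", "0", "gd1", "gd2", "D"))
  expect_equal(pedigree_completeness(ped, "X", depth = 1)$ipc, 1)

  # unknown sire -> 0 regardless of the dam side
  ped_nosire <- data.frame(animal_id = c("D", "X"),
                           sire_id = c("0", "0"), dam_id = c("0", "D"))
  expect_equal(pedigree_completeness(ped_nosire, "X", depth = 3)$ipc, 0)

  # sire with both parents known at g = 1 and nothing deeper, dam founder,
  # depth 2: C_s = (1/2) * (2/2 + 0/4) = 0.5, C_d = 0 -> IPC = 0
  toy <- data.frame(animal_id = c("pgs", "pgd", "S", "D", "X"),
                    sire_id = c("0", "0", "pgs", "0", "S"),
                    dam_id = c("0", "0", "pgd", "0", "D"))
  r <- pedigree_completeness(toy, "X", depth = 2)
  expect_equal(r$c_sire, 0.5)
  expect_equal(r$c_dam, 0)
  expect_equal(r$ipc, 0)

  # against the independent recursive enumeration, on a random pedigree
  ped_r <- random_pedigree(40, seed = 8)
  for (id in sample(ped_r$animal_id, 5)) {
    for (depth in c(2, 4)) {
      got <- pedigree_completeness(ped_r, id, depth = depth)
      side <- function(p) {
        if (p == "0") return(0)
        gens <- recurse_ancestors(ped_r, p, depth)
        sum(vapply(seq_len(depth),
                   function(g) length(gens[[g]]) / 2^g, 0)) / depth
      }
      cs <- side(ped_r$sire_id[match(id, ped_r$animal_id)])
      cd <- side(ped_r$dam_id[match(id, ped_r$animal_id)])
      expect_equal(got$c_sire, cs)
      expect_equal(got$c_dam, cd)
      expect_equal(got$ipc, if (cs + cd == 0) 0 else 2 * cs * cd / (cs + cd))
    }
  }
})

test_that("IPC is monotone under added ancestors and bounded in [0, 1]", {
  base <- data.frame(animal_id = c("S", "D", "X"),
                     sire_id = c("0", "0", "S"), dam_id = c("0", "0", "D"))
  ipc0 <- pedigree_completeness(base, "X", depth = 3)$ipc
  richer <- rbind(data.frame(animal_id = c("gs", "gd"),
                             sire_id = "0", dam_id = "0"), base)
  richer$sire_id[richer$animal_id == "S"] <- "gs"
  richer$dam_id[richer$animal_id == "S"] <- "gd"
  ipc1 <- pedigree_completeness(richer, "X", depth = 3)$ipc
  expect_gte(ipc1, ipc0)
  all_ipc <- pedigree_completeness(random_pedigree(60, seed = 2), depth = 4)$ipc
  expect_true(all(all_ipc >= 0 & all_ipc <= 1))
})

test_that("generations traced: max depth and complete-generation equivalents", {
  founders <- data.frame(animal_id = c("A", "B"), sire_id = "0", dam_id = "0")
  gt0 <- generations_traced(founders)
  expect_equal(gt0$summary$mean_max_depth, 0)
  expect_equal(gt0$summary$mean_cge, 0)

  # full 3-generation pedigree: depth 3, CGE = 3
  ids <- c(paste0("g3_", 1:8), paste0("g2_", 1:4), paste0("g1_", 1:2), "X")
  ped3 <- data.frame(
    animal_id = ids,
    sire_id = c(rep("0", 8), paste0("g3_", c(1, 3, 5, 7)), paste0("g2_", c(1, 3)), "g1_1"),
    dam_id  = c(rep("0", 8), paste0("g3_", c(2, 4, 6, 8)), paste0("g2_", c(2, 4)), "g1_2"))
  gt3 <- generations_traced(ped3, "X")
  expect_equal(gt3$per_animal$max_depth, 3L)
  expect_equal(gt3$per_animal$cge, 3)

  # random pedigree equals the recursion oracle (path enumeration is
  # exponential in depth, so keep the oracle's horizon modest)
  ped_r <- random_pedigree(25, seed = 21)
  got <- generations_traced(ped_r, max_generations = 14L)$per_animal
  for (id in sample(ped_r$animal_id, 6)) {
    gens <- recurse_ancestors(ped_r, id, 14)
    counts <- lengths(gens)
    exp_depth <- if (any(counts > 0)) max(which(counts > 0)) else 0L
    exp_cge <- sum(counts * 0.5^seq_along(counts))
    expect_equal(got$max_depth[got$animal_id == id], exp_depth)
    expect_equal(got$cge[got$animal_id == id], exp_cge)
  }
})

test_that("A-inverse matches closed forms and the tabular oracle", {
  one <- data.frame(animal_id = "A", sire_id = "0", dam_id = "0")
  expect_equal(as.matrix(a_inverse(one)), matrix(1, dimnames = list("A", "A")))

  trio <- trio_pedigree()
  Ai <- as.matrix(a_inverse(trio))
  expect_equal(Ai["O", "O"], 2)
  expect_equal(Ai["O", "S"], -1)
  expect_equal(Ai["O", "D"], -1)
  expect_equal(Ai["S", "S"], 1.5)
  expect_equal(Ai["D", "D"], 1.5)
  expect_equal(Ai["S", "D"], 0.5)

  # property: A-inverse equals the dense inverse of tabular A on random
  # pedigrees (with inbreeding: parents can be related)
  for (seed in c(1, 2, 3, 4, 5)) {
    ped <- random_pedigree(sample(10:50, 1), seed = seed)
    A <- a_tabular(ped)
    Ai <- as.matrix(a_inverse(ped))
    expect_lt(max(abs(Ai - solve(A))), 1e-8)
  }

  # cycle errors; unknown parent handled as missing
  cyc <- data.frame(animal_id = c("A", "B"), sire_id = c("B", "A"),
                    dam_id = c("0", "0"))
  expect_error(a_inverse(cyc), "cycle")
})

test_that("data-editing drops thin cells and under-represented groups", {
  phe <- small_herdbook()$phenotypes
  env <- small_herdbook()$env
  th <- edit_thresholds(min_obs_per_cell = 2, eg_min_levels_mt = 2,
                        eg_min_records_mt = 50)
  ed <- edit_data(phe, env, th, "MT")
  # no surviving class cell below the minimum
  for (term in c("heg_level", "htd", "parity_class")) {
    expect_true(all(table(ed$data[[term]]) >= 2))
  }
  # surviving EGs meet both thresholds
  eg_lv <- tapply(ed$data$herd_id, ed$data$eg_label,
                  function(h) length(unique(h)))
  expect_true(all(eg_lv >= 2))
  expect_true(all(table(ed$data$eg_label) >= 50))

  # idempotence
  ed2 <- edit_data(ed$data, env, th, "MT")
  expect_equal(nrow(ed2$data), nrow(ed$data))
  expect_equal(ed2$data$value, ed$data$value)

  expect_error(edit_data(phe, env, th, "XX"), "dataset_kind")
})

test_that("group-retention thresholds differ by dataset kind", {
  # 5 herd levels, 10000 records: dropped for MT (needs 6 levels),
  # retained for FS (needs 5 levels and 300 records)
  phe <- tibble::tibble(
    herd_id = rep(paste0("H", 1:5), each = 2000),
    eg_label = "EG1",
    heg_level = rep(paste0("H", 1:5), each = 2000),
    value = rnorm(10000)
  )
  ed_mt <- edit_data(phe, thresholds = edit_thresholds(), dataset_kind = "MT",
                     class_terms = character())
  expect_equal(nrow(ed_mt$data), 0L)
  ed_fs <- edit_data(phe, thresholds = edit_thresholds(), dataset_kind = "FS",
                     class_terms = character())
  expect_equal(nrow(ed_fs$data), 10000L)

  # a single-record cell of a class effect is removed
  phe2 <- tibble::tibble(
    herd_id = rep("H1", 11), eg_label = "EG1", heg_level = "H1",
    parity_class = c(rep("P1", 10), "P2"), value = rnorm(11)
  )
  ed2 <- edit_data(phe2, thresholds = edit_thresholds(eg_min_levels_mt = 1,
                                                      eg_min_records_mt = 1),
                   dataset_kind = "MT", class_terms = "parity_class")
  expect_equal(nrow(ed2$data), 10L)
  expect_false("P2" %in% ed2$data$parity_class)
})
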