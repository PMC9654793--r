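test_that("hinge H-bond check applies the 3.5 A limit with role complementarity", {
  tc <- make_toy_complex(1, "binder")
  rec <- tc$receptor
  Npos <- as.numeric(rec$atoms[rec$hinge$N, c("x", "y", "z")])
  u <- hingedock:::unit3(as.numeric(rec$atoms[rec$hinge$H, c("x", "y", "z")]) - Npos)
  at_d <- function(d, el, order = 2) {
    o <- Npos + d * u
    m <- molecule(data.frame(element = c(el, "C"),
                             x = c(o[1], o[1] + 1.3), y = c(o[2], o[2]),
                             z = c(o[3], o[3])),
                  data.frame(i = 1, j = 2, order = order), "probe")
    assign_atom_types(m, PARAMS)
  }
  r34 <- hinge_hbond_check(at_d(3.4, "O"), NULL, rec)
  expect_true(r34$pass)
  expect_equal(nrow(r34$contacts), 1)
  expect_equal(r34$contacts$hinge_atom, "N")
  expect_lte(r34$contacts$distance, 3.5)
  # same geometry at 3.6 A fails
  expect_false(hinge_hbond_check(at_d(3.6, "O"), NULL, rec)$pass)
  # nonpolar carbon at 3.0 A fails on role mismatch
  expect_false(hinge_hbond_check(at_d(3.0, "C", order = 1), NULL, rec)$pass)
  norec <- tc$receptor; norec$hinge <- NULL
  expect_error(hinge_hbond_check(at_d(3.0, "O"), NULL, norec), "hinge")
})

test_that("two-step screen flags exactly the planted binders and keeps stage nesting", {
  tc <- make_toy_complex(1, "binder")
  g <- build_grids(tc$receptor, grid_box(c(-1, 0.2, 0), 9, 0.375), PARAMS,
                   types = c("C", "OA"))
  lib <- make_library(3, 16, 0.25)
  cfg <- screen_config(n_energy_slice = Inf, n_runs = 3, seed = 7,
                       search_cfg = dock_config(pop_size = 28, n_gens = 30,
                                                local_steps = 80))
  rep <- run_screen(lib$molecules, tc$receptor, g, PARAMS, cfg)
  m <- merge(rep$table, lib$labels, by = "id")
  expect_identical(m$hinge_pass, m$binder)
  # monotone filtration: hinge => slice => ro5
  expect_true(all(!m$hinge_pass | m$energy_slice_pass))
  expect_true(all(!m$energy_slice_pass | m$ro5_pass))
  # summary counts equal flag tallies
  expect_equal(unname(rep$summary["n_ro5"]), sum(m$ro5_pass))
  expect_equal(unname(rep$summary["n_energy_slice"]), sum(m$energy_slice_pass))
  expect_equal(unname(rep$summary["n_final_hits"]), sum(m$hinge_pass))
  # ranks are 1..n_docked without gaps
  expect_identical(sort(m$rank[!is.na(m$rank)]), seq_len(sum(!is.na(m$rank))))

  # a zero-size energy slice reports zero hits but still counts stages
  rep0 <- run_screen(lib$molecules, tc$receptor, g, PARAMS,
                     within(cfg, n_energy_slice <- 0))
  expect_equal(unname(rep0$summary["n_final_hits"]), 0)
  expect_equal(unname(rep0$summary["n_ro5"]), sum(m$ro5_pass))

  # permuting the library changes no ranks or flags
  perm <- rev(seq_along(lib$molecules))
  repp <- run_screen(lib$molecules[perm], tc$receptor, g, PARAMS, cfg)
  a <- rep$table[order(rep$table$id), ]
  b <- repp$table[order(repp$table$id), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)

  # shrinking the slice never grows the final hit set
  rep2 <- run_screen(lib$molecules, tc$receptor, g, PARAMS,
                     within(cfg, n_energy_slice <- 2))
  hits_full <- rep$table$id[rep$table$hinge_pass]
  hits_small <- rep2$table$id[rep2$table$hinge_pass]
  expect_true(all(hits_small %in% hits_full))
})

test_that("screening report export writes the table and the JSON summary", {
  tc <- make_toy_complex(1, "binder")
  g <- build_grids(tc$receptor, grid_box(c(-1, 0.2, 0), 11, 0.5), PARAMS,
                   types = c("C", "OA"))
  lib <- make_library(4, 4, 0.5)
  cfg <- screen_config(n_runs = 1, seed = 2,
                       search_cfg = dock_config(pop_size = 10, n_gens = 8,
                                                local_steps = 10))
  rep <- run_screen(lib$molecules, tc$receptor, g, PARAMS, cfg)
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  export_report(rep, tsv = tsv, json = js)
  tab <- utils::read.delim(tsv)
  expect_equal(nrow(tab), 4)
  expect_equal(jsonlite::read_json(js)$n_library, 4)
})
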