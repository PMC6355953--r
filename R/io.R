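.panel_columns <- c("session_id", "player_id", "round", "group_id",
                    "treatment", "r", "contribution", "payoff", "is_robot")

#' Write a panel to CSV
#'
#' @param panel A long-format panel.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(all(.panel_columns %in% names(panel)))
  utils::write.csv(panel[.panel_columns], path, row.names = FALSE)
  invisible(path)
}

#' Validate a long-format panel
#'
#' Checks the structural invariants of the panel schema: required columns,
#' integer contributions within `[0, endowment]`, one record per (player,
#' round) with complete rounds, exactly `group_size` members per (session,
#' round, group), zero contributions from robots, and payoffs consistent
#' with the public-goods payoff equation `g = w - c + r G / n` within
#' `tol`. A `column_map` may remap arbitrary headers onto the canonical
#' schema before validation.
#'
#' @param panel A `data.frame`.
#' @param config A [game_config()] supplying `group_size` and `endowment`.
#' @param tol Tolerance for the payoff cross-check.
#' @param column_map Optional named character vector `c(canonical = found)`.
#' @return A `data.frame` of violations with columns `row`, `check`,
#'   `message`; zero rows when the panel is valid.
#' @export
validate_panel <- function(panel, config = game_config(), tol = 1e-6,
                           column_map = NULL) {
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(panel)[names(panel) == column_map[[canon]]] <- canon
    }
  }
  problems <- list()
  note <- function(row, check, message) {
    problems[[length(problems) + 1L]] <<- data.frame(
      row = row, check = check, message = message, stringsAsFactors = FALSE)
  }
  miss <- setdiff(.panel_columns, names(panel))
  if (length(miss)) {
    note(NA_integer_, "columns",
         paste("missing columns:", paste(miss, collapse = ", ")))
    return(do.call(rbind, problems))
  }
  w <- config$endowment
  gs <- config$group_size
  bad <- which(!is.finite(panel$contribution) |
                 panel$contribution != round(panel$contribution) |
                 panel$contribution < 0 | panel$contribution > w)
  for (i in bad) {
    note(i, "contribution",
         sprintf("contribution %s outside integer range [0, %d]",
                 format(panel$contribution[i]), w))
  }
  rob <- which(panel$is_robot & panel$contribution != 0)
  for (i in rob) note(i, "robot", "robot with non-zero contribution")

  dup <- duplicated(panel[c("player_id", "round")])
  for (i in which(dup)) note(i, "duplicate", "duplicate (player, round) record")

  for (p in unique(panel$player_id)) {
    rounds <- sort(panel$round[panel$player_id == p])
    expected <- seq(min(rounds), max(rounds))
    missing_rounds <- setdiff(expected, rounds)
    if (length(missing_rounds)) {
      note(NA_integer_, "rounds",
           sprintf("player %s missing round(s) %s", p,
                   paste(missing_rounds, collapse = ", ")))
    }
  }

  key <- paste(panel$session_id, panel$round, panel$group_id)
  if (length(bad) == 0L) {
    for (k in unique(key)) {
      sel <- which(key == k)
      if (length(sel) != gs) {
        note(sel[1L], "group_size",
             sprintf("group %s has %d members, expected %d", k, length(sel), gs))
        next
      }
      r <- panel$r[sel][1L]
      expected <- w - panel$contribution[sel] +
        r * sum(panel$contribution[sel]) / gs
      off <- abs(panel$payoff[sel] - expected) > tol
      for (j in which(off)) {
        note(sel[j], "payoff",
             sprintf("payoff %.6f contradicts the payoff equation (expected %.6f)",
                     panel$payoff[sel][j], expected[j]))
      }
    }
  }
  if (length(problems) == 0L) {
    return(data.frame(row = integer(0), check = character(0),
                      message = character(0)))
  }
  do.call(rbind, problems)
}

#' Read and validate a panel CSV
#'
#' @param path CSV path with the canonical header (see [write_panel()]),
#'   or arbitrary headers remapped through `column_map`.
#' @inheritParams validate_panel
#' @return The validated panel `data.frame`.
#' @export
read_panel <- function(path, config = game_config(), tol = 1e-6,
                       column_map = NULL) {
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  report <- validate_panel(panel, config, tol, column_map)
  if (nrow(report) > 0L) {
    cond <- structure(
      class = c("pggmarkov_validation_error", "error", "condition"),
      list(message = paste0(
        "panel failed validation (", nrow(report), " problem(s)); first: ",
        report$message[1L],
        if (!is.na(report$row[1L])) sprintf(" [row %d]", report$row[1L]) else ""),
        call = sys.call(-1), report = report))
    stop(cond)
  }
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(panel)[names(panel) == column_map[[canon]]] <- canon
    }
  }
  panel
}

#' Serialize a fitted transition model to JSON
#'
#' @param model A [fit_markov_model()] object.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "markov_fit"))
  obj <- unclass(model)
  if (!is.null(obj$coef)) {
    obj$coef_dim <- dim(obj$coef)
    obj$coef <- as.numeric(obj$coef)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(obj$coef)) {
    obj$coef <- array(obj$coef, dim = obj$coef_dim,
                      dimnames = list(origin = level_labels,
                                      dest = level_labels[-1L],
                                      term = obj$terms))
    obj$coef_dim <- NULL
  }
  if (!is.null(obj$matrices)) {
    obj$matrices <- lapply(obj$matrices, function(m) {
      M <- as.matrix(m); dimnames(M) <- list(level_labels, level_labels); M
    })
  }
  obj$window <- as.list(obj$window)
  obj$n_rounds <- as.integer(obj$n_rounds)
  structure(obj, class = "markov_fit")
}

#' Run the full analysis pipeline on a simulated study
#'
#' Chains simulate - describe - fit - test - flux - cluster and writes
#' every intermediate artifact to `out_dir`: the panel CSV, per-treatment
#' descriptive summaries, the pooled and treatment-augmented transition
#' models with their likelihood-ratio test, the per-round flux toward the
#' Nash state, cluster assignments at `k` clusters for the homogeneous
#' treatment, and a manifest recording the seed, configuration hash and
#' package version. Outputs are deterministic given `seed`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed.
#' @param sizes_homogeneous,sizes_heterogeneous Session sizes.
#' @param drift Generator drift (see [make_reference_generator()]).
#' @param terms_alt Covariate terms of the alternative model; the null
#'   model drops the treatment terms.
#' @param k Cluster count for the homogeneous cut.
#' @param n_rounds Rounds per session.
#' @return Invisibly, a list with the in-memory results and file paths.
#' @export
run_pipeline <- function(out_dir, seed = 1L,
                         sizes_homogeneous = c(13L, 16L, 7L),
                         sizes_heterogeneous = c(14L, 14L, 7L),
                         drift = 0,
                         terms_alt = c("round", "treatment"),
                         k = 4L, n_rounds = 30L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(seed = seed, sizes_homogeneous = sizes_homogeneous,
              sizes_heterogeneous = sizes_heterogeneous, drift = drift,
              terms_alt = terms_alt, k = k, n_rounds = n_rounds)
  stage <- "simulate"
  paths <- list()
  result <- tryCatch({
    panel <- simulate_study(seed, sizes_homogeneous, sizes_heterogeneous,
                            drift = drift, n_rounds = n_rounds)
    paths$panel <- file.path(out_dir, "panel.csv")
    write_panel(panel, paths$panel)

    stage <- "describe"
    desc <- list()
    for (trt in unique(panel$treatment)) {
      sub <- panel[panel$treatment == trt, ]
      d <- merge(mean_contribution_by_round(sub, r_filter = 2),
                 level_shares_by_round(sub, r_filter = 2), by = c("round", "n"))
      f <- file.path(out_dir, sprintf("descriptives_%s_r2.csv", trt))
      utils::write.csv(d, f, row.names = FALSE)
      desc[[trt]] <- d
      paths[[paste0("descriptives_", trt)]] <- f
    }

    stage <- "fit"
    null_model <- fit_markov_model(panel, r_filter = 2,
                                   terms = setdiff(terms_alt, c("treatment", "round:treatment")),
                                   n_rounds = n_rounds)
    alt_model <- fit_markov_model(panel, r_filter = 2, terms = terms_alt,
                                  n_rounds = n_rounds)
    paths$model_null <- file.path(out_dir, "model_null.json")
    paths$model_alt <- file.path(out_dir, "model_alt.json")
    write_model(null_model, paths$model_null)
    write_model(alt_model, paths$model_alt)

    stage <- "lrt"
    test <- lrt(null_model, alt_model)
    paths$lrt <- file.path(out_dir, "lrt.json")
    jsonlite::write_json(test[c("statistic", "df", "p_value")], paths$lrt,
                         auto_unbox = TRUE, digits = NA)

    stage <- "flux"
    flux_rows <- list()
    for (trt in unique(panel$treatment)) {
      sub <- panel[panel$treatment == trt, ]
      shares <- level_shares_by_round(sub, r_filter = 2)
      init <- as.numeric(shares[1L, paste0("share_", level_labels)]) / 100
      fx <- flux_to_nash(alt_model, game_config("homogeneous", n_rounds = n_rounds),
                         initial = init, treatment = trt, r = 2)
      flux_rows[[trt]] <- data.frame(treatment = trt, fx)
    }
    flux_tab <- do.call(rbind, flux_rows)
    rownames(flux_tab) <- NULL
    paths$flux <- file.path(out_dir, "flux.csv")
    utils::write.csv(flux_tab, paths$flux, row.names = FALSE)

    stage <- "cluster"
    hom <- panel[panel$treatment == "homogeneous", ]
    dend <- complete_linkage(trajectory_distances(hom))
    assign <- cut_clusters(dend, k)
    prof <- cluster_profiles(assign, hom)
    paths$clusters <- file.path(out_dir, "clusters.csv")
    utils::write.csv(data.frame(player_id = names(assign), cluster = assign),
                     paths$clusters, row.names = FALSE)
    paths$cluster_profiles <- file.path(out_dir, "cluster_profiles.csv")
    utils::write.csv(prof, paths$cluster_profiles, row.names = FALSE)
    paths$dendrogram <- file.path(out_dir, "dendrogram.nwk")
    write_newick(dend, paths$dendrogram)

    stage <- "manifest"
    manifest <- list(package = "pggmarkov",
                     version = as.character(utils::packageVersion("pggmarkov")),
                     seed = seed, config = cfg, config_hash = rlang::hash(cfg))
    paths$manifest <- file.path(out_dir, "manifest.json")
    jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)

    list(panel = panel, descriptives = desc, null_model = null_model,
         alt_model = alt_model, lrt = test, flux = flux_tab,
         clusters = assign, cluster_profiles = prof, manifest = manifest,
         paths = paths)
  }, error = function(e) {
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
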