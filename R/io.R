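# Delimited-file readers/writers and the YAML run configuration.

#' Read a feature table from CSV inputs
#'
#' Expects three files: `features` (a `subject_id` column plus one numeric
#' column per ROI feature), `networkMap` (columns `feature_id`,
#' `network_id`) and `labels` (columns `subject_id`, `group`).  Validates
#' that every feature is mapped, every subject labelled exactly once, and
#' that each network carries the same number of features.
#'
#' @param features,networkMap,labels paths to the three CSV files.
#' @return A [RoiFeatureSet-class].
#' @export
readFeatureInputs <- function(features, networkMap, labels) {
  for (p in c(features, networkMap, labels)) {
    if (!file.exists(p)) stop("input file not found: ", p)
  }
  ft <- read.csv(features, check.names = FALSE)
  if (!"subject_id" %in% names(ft)) {
    stop(features, ": missing 'subject_id' column")
  }
  ids <- as.character(ft$subject_id)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(features, ": duplicate subject id '", dup[1], "'")
  vals <- as.matrix(ft[, setdiff(names(ft), "subject_id"), drop = FALSE])
  if (!is.numeric(vals)) stop(features, ": feature columns must be numeric")
  rownames(vals) <- ids

  nm <- read.csv(networkMap)
  if (!all(c("feature_id", "network_id") %in% names(nm))) {
    stop(networkMap, ": needs columns 'feature_id' and 'network_id'")
  }
  missing <- setdiff(colnames(vals), nm$feature_id)
  if (length(missing)) {
    stop(networkMap, ": no network assignment for feature '",
         missing[1], "'")
  }
  net <- nm$network_id[match(colnames(vals), nm$feature_id)]

  lb <- read.csv(labels)
  if (!all(c("subject_id", "group") %in% names(lb))) {
    stop(labels, ": needs columns 'subject_id' and 'group'")
  }
  unlabelled <- setdiff(ids, lb$subject_id)
  if (length(unlabelled)) {
    stop(labels, ": no group label for subject '", unlabelled[1], "'")
  }
  grp <- lb$group[match(ids, lb$subject_id)]
  RoiFeatureSet(vals, network = net, groups = grp,
                subjectIds = ids, featureIds = colnames(vals))
}

#' Write a RoiFeatureSet as the three-CSV input bundle
#'
#' Inverse of [readFeatureInputs()]: writes `features.csv`,
#' `network_map.csv` and `labels.csv` into `dir`.
#'
#' @param x a [RoiFeatureSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the three paths.
#' @export
writeFeatureInputs <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  vals <- featureMatrix(x)
  ft <- data.frame(subject_id = rownames(vals), vals, check.names = FALSE)
  nm <- data.frame(feature_id = colnames(vals), network_id = networkMap(x))
  lb <- data.frame(subject_id = rownames(vals),
                   group = as.character(groups(x)))
  paths <- file.path(dir, c("features.csv", "network_map.csv", "labels.csv"))
  write.csv(ft, paths[1], row.names = FALSE)
  write.csv(nm, paths[2], row.names = FALSE)
  write.csv(lb, paths[3], row.names = FALSE)
  invisible(paths)
}

# Recognised configuration schema: name -> default.  NULL defaults are
# required-at-use, not required-at-parse.
runConfigDefaults <- function() {
  list(
    mode = "features",
    inputs = list(features = NULL, network_map = NULL, labels = NULL),
    output_dir = ".",
    synthetic = list(m1 = 40, m2 = 40, L = 4, n = 3, rho = 0.5,
                     affected = 1, effect_size = 2, rho_shift = 0,
                     noise_sd = 0.1, voxels_per_roi = 50, mixing_sd = 0.5),
    extraction = list(alpha = 0.05, z_threshold = 3, top_k = 3),
    coupling = list(E1 = 3, E2 = 2, E1_grid = c(2, 3, 4),
                    E2_grid = c(1, 2, 3, 4, 5), alpha = 0.05,
                    scale = TRUE, transductive = FALSE),
    classifier = list(C = 1, rounds = 1, folds = 10, positive = "AD"),
    seed = 1
  )
}

mergeConfig <- function(defaults, user, path = "") {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key: ", path, unknown[1])
  }
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- mergeConfig(defaults[[nm]],
                                    as.list(user[[nm]]),
                                    paste0(path, nm, "."))
    } else {
      defaults[nm] <- user[nm]
    }
  }
  defaults
}

#' Read and validate a YAML run configuration
#'
#' Unknown keys are rejected with an error naming the key; omitted keys
#' take package defaults.
#'
#' @param path YAML file path (or `NULL` for pure defaults).
#' @return a nested configuration list.
#' @export
readRunConfig <- function(path = NULL) {
  defaults <- runConfigDefaults()
  if (is.null(path)) return(defaults)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(defaults)
  mergeConfig(defaults, user)
}

#' Write the resolved configuration beside outputs
#'
#' @param config configuration list.
#' @param dir output directory.
#' @return invisibly, the written path.
#' @export
writeResolvedConfig <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- file.path(dir, "resolved_config.yaml")
  yaml::write_yaml(config, p)
  invisible(p)
}

#' Write a grid-search report in the benchmark-table layout
#'
#' Rows are the three metrics (as percent), columns the representation
#' kind and (E1, E2) cell.
#'
#' @param grid data.frame from [gridSearch()].
#' @param path output CSV path.
#' @return invisibly, `path`.
#' @export
writeGridReport <- function(grid, path) {
  lab <- ifelse(is.na(grid$E1), grid$kind,
                ifelse(is.na(grid$E2),
                       sprintf("%s(E1=%d)", grid$kind, grid$E1),
                       sprintf("%s(E1=%d,E2=%d)", grid$kind, grid$E1,
                               grid$E2)))
  tab <- rbind(`ACC (%)` = round(100 * grid$accuracy, 2),
               `SEN (%)` = round(100 * grid$sensitivity, 2),
               `SPE (%)` = round(100 * grid$specificity, 2))
  colnames(tab) <- lab
  out <- data.frame(metric = rownames(tab), tab, check.names = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
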