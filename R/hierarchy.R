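#' Assemble trained class models into a prediction tree
#'
#' @param models list of `ec_class_model` objects (any order).
#' @return object of class `model_tree`: models indexed by EC string
#'   plus a parent-to-children index derived from EC algebra.
#' @export
model_tree <- function(models) {
  ecs <- vapply(models, function(m) m$ec, "")
  if (anyDuplicated(ecs)) stop("duplicate class models: ",
                               paste(ecs[duplicated(ecs)], collapse = ", "))
  names(models) <- ecs
  children <- list()
  for (ec in ecs) {
    lev <- ec_level(ec)
    if (lev >= 2L) {
      p <- ec_format(ec_parent(ec))
      if (!p %in% ecs) {
        stop("model for ", ec, " has no parent model ", p, " in the tree")
      }
      children[[p]] <- c(children[[p]], ec)
    }
  }
  structure(list(models = models[ec_sort_strings(ecs)], children = children),
            class = "model_tree")
}

#' @export
print.model_tree <- function(x, ...) {
  lev <- vapply(names(x$models), ec_level, integer(1))
  cat("<model_tree> ", length(x$models), " class models (",
      paste(sprintf("L%d:%d", sort(unique(lev)), table(lev)), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

#' One level of the hierarchical decision
#'
#' Scores a query against sibling candidate models and applies the
#' decision rules of one level: accept the maximum-scoring candidate
#' among those strictly above their class-specific positive cutoffs
#' (ties broken toward the lexicographically smallest EC number); if
#' none is above its positive cutoff but `check_negative` is set (the
#' enzyme / non-enzyme gate at the top level) and every score is
#' strictly below the negative cutoff, report `below_negative`;
#' otherwise report `none_above_cutoff`.
#'
#' @param query named (by id) length-1 character vector: the query
#'   sequence.
#' @param candidates list of class models sharing one level.
#' @param check_negative apply the negative-cutoff rule (top level
#'   only).
#' @return list with `decision` (`"accept"`, `"none_above_cutoff"` or
#'   `"below_negative"`), `ec` and `score` of the accepted class (NA
#'   otherwise) and the named vector `scores` of all candidates.
#' @export
predict_level <- function(query, candidates, check_negative = FALSE) {
  if (length(candidates) == 0L) stop("no candidate models at this level")
  ecs <- vapply(candidates, function(m) m$ec, "")
  scores <- vapply(candidates, function(m)
    model_weighted_scores(m, query), numeric(1))
  names(scores) <- ecs
  cutoffs <- vapply(candidates, function(m) m$positive_cutoff, numeric(1))
  above <- scores > cutoffs
  if (any(above)) {
    cand <- which(above)
    best <- max(scores[cand])
    winners <- cand[scores[cand] == best]
    win <- winners[match(ec_sort_strings(ecs[winners])[1], ecs[winners])]
    return(list(decision = "accept", ec = ecs[win],
                score = unname(scores[win]), scores = scores))
  }
  if (check_negative) {
    negs <- vapply(candidates, function(m) m$negative_cutoff, numeric(1))
    if (all(scores < negs)) {
      return(list(decision = "below_negative", ec = NA_character_,
                  score = NA_real_, scores = scores))
    }
  }
  list(decision = "none_above_cutoff", ec = NA_character_,
       score = NA_real_, scores = scores)
}

#' Hierarchical prediction for one query protein
#'
#' Top-down traversal of the model tree.  The top level is the joint
#' enzyme / non-enzyme and main-class decision: acceptance of a main
#' class sends the query down into that class's children; scores below
#' the negative cutoff for every main class label the query
#' `"non-enzyme"`; anything in between is `"no prediction"`.  At
#' deeper levels the query either descends into the accepted child, or
#' finalizes with the EC number accepted at the previous level when no
#' child clears its positive cutoff (or none was trainable).  The
#' confidence is the weighted ensemble score of the deepest accepted
#' class.
#'
#' @param tree a [model_tree()].
#' @param sequence sanitized query sequence.
#' @param id query identifier.
#' @return list with `protein_id`, `label` (EC string, `"non-enzyme"`
#'   or `"no prediction"`), `confidence`, and `per_level` (list of
#'   per-level candidate scores, for audit).
#' @export
predict_protein <- function(tree, sequence, id = "query") {
  query <- setNames(sequence, id)
  top <- tree$models[vapply(names(tree$models), ec_level, integer(1)) == 1L]
  if (length(top) == 0L) stop("model tree has no top-level models")
  audit <- list()
  lev <- predict_level(query, unname(top), check_negative = TRUE)
  audit[["1"]] <- lev$scores
  if (lev$decision == "below_negative") {
    return(list(protein_id = id, label = "non-enzyme", confidence = NA_real_,
                per_level = audit))
  }
  if (lev$decision == "none_above_cutoff") {
    return(list(protein_id = id, label = "no prediction",
                confidence = NA_real_, per_level = audit))
  }
  accepted <- lev$ec
  confidence <- lev$score
  repeat {
    kids <- tree$children[[accepted]]
    if (is.null(kids) || length(kids) == 0L) break
    nxt <- predict_level(query, unname(tree$models[kids]),
                         check_negative = FALSE)
    audit[[as.character(ec_level(kids[1]))]] <- nxt$scores
    if (nxt$decision != "accept") break  # finalize at the previous level
    accepted <- nxt$ec
    confidence <- nxt$score
  }
  list(protein_id = id, label = accepted, confidence = confidence,
       per_level = audit)
}

#' Hierarchical predictions for a set of proteins
#'
#' @param tree a [model_tree()].
#' @param records data frame with columns `id` and `sequence`.
#' @return data frame with columns `protein_id`, `label`,
#'   `confidence`; the per-query audit trails are attached as
#'   attribute `"details"`.
#' @export
predict_sequences <- function(tree, records) {
  res <- lapply(seq_len(nrow(records)), function(i) {
    predict_protein(tree, records$sequence[i], records$id[i])
  })
  out <- data.frame(
    protein_id = vapply(res, `[[`, "", "protein_id"),
    label = vapply(res, `[[`, "", "label"),
    confidence = vapply(res, `[[`, numeric(1), "confidence"),
    stringsAsFactors = FALSE)
  attr(out, "details") <- lapply(res, `[[`, "per_level")
  out
}

#' Train the full model tree from annotated protein records
#'
#' The end-to-end training pipeline:
#' \enumerate{
#'   \item propagate EC annotations up the hierarchy and discard
#'     multi-EC proteins ([propagate_annotations()]);
#'   \item select classes with at least `min_class_size` members and
#'     the reliable non-enzymes;
#'   \item redundancy-cluster each main class's members and the
#'     non-enzymes ([reduce_redundancy()]) and split whole clusters
#'     90/10 into global train / validation id sets, so no
#'     near-duplicate pair crosses the split anywhere in the tree;
#'   \item per class: positives are its members on each side of the
#'     split; negatives are drawn balanced (equal to the positive
#'     count) from the hierarchy-aware negative pool
#'     ([build_negative_pool()]), with the configured
#'     sibling / other-main / non-enzyme mix, train negatives from the
#'     train side and validation negatives from the validation side;
#'   \item train the per-class ensemble ([train_class_model()]).
#' }
#'
#' @param records protein record data frame (`id`, `sequence`, `ec`,
#'   `annotation_score`, `is_enzyme`).
#' @param config an [ec_config()].
#' @param verbose print per-class progress to stderr.
#' @return a [model_tree()] with attributes `"split"` (the global
#'   train/validation id sets) and `"datasets"` (the per-class
#'   [class_dataset()]s).
#' @export
train_model_tree <- function(records, config = ec_config(), verbose = TRUE) {
  say <- function(...) if (verbose) message(...)
  records$sequence <- mapply(sanitize_sequence, records$sequence,
                             id = records$id,
                             MoreArgs = list(policy = config$residue_policy),
                             USE.NAMES = FALSE)
  sequences <- setNames(records$sequence, records$id)

  class_map <- propagate_annotations(records)
  classes <- select_trainable_classes(class_map, config$min_class_size)
  if (length(classes) == 0L) stop("no trainable classes (min_class_size = ",
                                  config$min_class_size, ")")
  nonenzymes <- select_nonenzymes(records, config$min_annotation_score)
  say(length(classes), " trainable classes; ", length(nonenzymes),
      " reliable non-enzymes")

  # global cluster-atomic split: per main class plus the non-enzymes
  main_keys <- names(class_map)[vapply(names(class_map), ec_level,
                                       integer(1)) == 1L]
  groups <- c(lapply(main_keys, function(k) class_map[[k]]),
              list(nonenzymes))
  names(groups) <- c(main_keys, "non-enzyme")
  global_train <- character(0)
  global_val <- character(0)
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (length(ids) == 0L) next
    cl <- reduce_redundancy(records[match(ids, records$id), , drop = FALSE],
                            config$identity_threshold,
                            config$gap_open_global, config$gap_ext_global)
    sp <- split_train_validation(cl, config$val_fraction,
                                 seed = derive_seed(config$seed,
                                                    paste0("split-", g)),
                                 use_representatives = config$use_representatives)
    global_train <- c(global_train, sp$train)
    global_val <- c(global_val, sp$validation)
    say("split ", g, ": ", length(cl$clusters), " clusters -> ",
        length(sp$train), " train / ", length(sp$validation), " validation")
  }

  ne_train <- intersect(nonenzymes, global_train)
  ne_val <- intersect(nonenzymes, global_val)

  models <- vector("list", length(classes))
  datasets <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    ec <- classes[i]
    mix <- if (ec_level(ec) == 1L) config$mix_main else config$mix_sub
    if (config$wne) mix <- apply_wne(mix)
    pool <- build_negative_pool(ec, class_map, nonenzymes)
    pool_train <- lapply(pool, intersect, global_train)
    pool_val <- lapply(pool, intersect, global_val)
    pos_train <- intersect(class_map[[ec]], global_train)
    pos_val <- intersect(class_map[[ec]], global_val)
    neg_train <- sample_balanced_negatives(
      pool_train, length(pos_train), mix,
      seed = derive_seed(config$seed, paste0("neg-train-", ec)))
    neg_val <- sample_balanced_negatives(
      pool_val, length(pos_val), mix,
      seed = derive_seed(config$seed, paste0("neg-val-", ec)))
    ds <- class_dataset(ec, pos_train, neg_train, pos_val, neg_val,
                        composition_train = attr(neg_train, "composition"),
                        composition_val = attr(neg_val, "composition"))
    say("training ", ec, ": +", length(pos_train), "/-", length(neg_train),
        " train, +", length(pos_val), "/-", length(neg_val), " validation")
    m <- train_class_model(ds, sequences, config)
    say("  AUROC ", paste(sprintf("%s=%.3f", names(m$auroc), m$auroc),
                          collapse = " "),
        "; positive cutoff ", sprintf("%.2f", m$positive_cutoff))
    models[[i]] <- m
    datasets[[i]] <- ds
  }
  tree <- model_tree(models)
  attr(tree, "split") <- list(train = global_train, validation = global_val,
                              nonenzyme_train = ne_train,
                              nonenzyme_val = ne_val)
  attr(tree, "datasets") <- setNames(datasets, classes)
  tree
}

#' Save / load a model tree
#'
#' The trained tree is serialized into a directory: an RDS file with
#' the models plus a JSON summary (classes, AUROCs, weights, cutoffs)
#' for inspection.
#'
#' @param tree a [model_tree()].
#' @param dir directory path (created if needed).
#' @export
save_model_tree <- function(tree, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(tree, file.path(dir, "model_tree.rds"))
  summary <- lapply(tree$models, function(m) {
    list(ec = m$ec, auroc = as.list(m$auroc), weights = as.list(m$weights),
         positive_cutoff = m$positive_cutoff,
         negative_cutoff = m$negative_cutoff,
         negative_composition = m$composition)
  })
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname save_model_tree
#' @export
load_model_tree <- function(dir) {
  path <- file.path(dir, "model_tree.rds")
  if (!file.exists(path)) stop("no model tree found under ", dir)
  readRDS(path)
}
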