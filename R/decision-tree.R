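# Stage-3: greedy classification-tree integration of the composite
# biomarker, biomarker frequency, practitioner (EAE Hub) diagnosis and
# diagnostic certainty; three-way terminal decisions (diagnose autism /
# rule out / refer); evaluation over decided cases; stratified k-fold
# cross-validation. Growth is best-first with a total-split budget, so
# "stop after m splits" has its literal meaning.

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  1 - sum(p^2)
}

entropy_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  p <- counts / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

node_counts <- function(y) c(autism = sum(y), nonautism = sum(!y))

# All candidate binary splits of one feature at one node, with children
# index masks. Numeric features split as (x <= t | x > t) over unique
# values; binary categorical features have their single partition.
candidate_splits <- function(x, feature) {
  if (is.logical(x)) x <- as.numeric(x)
  if (is.numeric(x)) {
    vals <- sort(unique(x))
    if (length(vals) < 2) return(list())
    lapply(vals[-length(vals)], function(t)
      list(variable = feature, type = "numeric", threshold = t,
           left = x <= t,
           label = sprintf("%s<=%g", feature, t)))
  } else {
    x <- as.character(x)
    lv <- sort(unique(x))
    if (length(lv) < 2) return(list())
    if (length(lv) > 2)
      stop("categorical feature `", feature, "` must be binary",
           call. = FALSE)
    list(list(variable = feature, type = "categorical",
              left_values = lv[1], left = x == lv[1],
              label = sprintf("%s=%s", feature, lv[1])))
  }
}

#' Fit a classification tree by greedy recursive partitioning
#'
#' Binary CART on a two-class outcome. Growth is best-first: at each step
#' the split with the greatest impurity decrease over all current leaves is
#' taken, so `max_splits` caps the total number of splits in the tree
#' (a tree with m splits has m + 1 leaves). A split is accepted only when
#' both children have at least `min_node` cases and the absolute impurity
#' decrease is at least `cp` times the root impurity. Ties between
#' equal-gain splits are broken by the fixed feature order given in
#' `features`, then by the lower threshold — fitting is deterministic.
#'
#' @param data data.frame of cases.
#' @param outcome Name of the binary outcome column (event = `positive`
#'   level for character columns, TRUE for logical).
#' @param features Feature columns, in tie-break order; numeric/logical
#'   features split on thresholds, character features must be binary.
#' @param max_splits Total split budget.
#' @param min_node Minimum child size.
#' @param criterion `"gini"` (default) or `"entropy"`.
#' @param cp Minimum impurity decrease, as a fraction of the root impurity.
#' @param positive Outcome level treated as the event.
#' @return Object of class `cart_tree`: list of nodes (each with `id`,
#'   `counts`, `split` or `terminal`), feature metadata, and `n_splits`.
#' @export
fit_cart <- function(data, outcome, features, max_splits = 5L,
                     min_node = 5L, criterion = c("gini", "entropy"),
                     cp = 0.01, positive = "autism") {
  criterion <- match.arg(criterion)
  imp <- if (criterion == "gini") gini_impurity else entropy_impurity
  stopifnot(is.data.frame(data), outcome %in% names(data),
            all(features %in% names(data)), max_splits >= 0)
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == positive
  y <- as.logical(y)
  stopifnot(!anyNA(y))
  for (f in features) if (anyNA(data[[f]]))
    stop("feature `", f, "` has missing values", call. = FALSE)

  root_gain_floor <- cp * nrow(data) * imp(node_counts(y))
  nodes <- list()
  new_node <- function(rows, depth) {
    id <- length(nodes) + 1L
    nodes[[id]] <<- list(id = id, rows = rows, depth = depth,
                         counts = node_counts(y[rows]), terminal = TRUE,
                         split = NULL, children = NULL)
    id
  }
  new_node(seq_len(nrow(data)), 0L)

  best_split_of <- function(node) {
    rows <- node$rows
    if (length(unique(y[rows])) < 2) return(NULL)
    base <- length(rows) * imp(node_counts(y[rows]))
    best <- NULL
    for (f in features) {
      for (sp in candidate_splits(data[[f]][rows], f)) {
        nl <- sum(sp$left); nr <- length(rows) - nl
        if (nl < min_node || nr < min_node) next
        gain <- base -
          (nl * imp(node_counts(y[rows][sp$left])) +
             nr * imp(node_counts(y[rows][!sp$left])))
        better <- is.null(best) || gain > best$gain + 1e-12
        if (better) best <- c(sp, list(gain = gain))
      }
    }
    if (!is.null(best) && best$gain >= max(root_gain_floor, 1e-12)) best
    else NULL
  }

  n_splits <- 0L
  while (n_splits < max_splits) {
    leaf_ids <- which(vapply(nodes, `[[`, TRUE, "terminal"))
    cands <- lapply(leaf_ids, function(i) best_split_of(nodes[[i]]))
    ok <- !vapply(cands, is.null, TRUE)
    if (!any(ok)) break
    gains <- vapply(cands[ok], `[[`, 1.0, "gain")
    pick <- which(ok)[which.max(gains)]       # first max: deterministic
    id <- leaf_ids[pick]
    sp <- cands[[pick]]
    rows <- nodes[[id]]$rows
    left_id <- new_node(rows[sp$left], nodes[[id]]$depth + 1L)
    right_id <- new_node(rows[!sp$left], nodes[[id]]$depth + 1L)
    sp$left <- NULL
    nodes[[id]]$split <- sp
    nodes[[id]]$terminal <- FALSE
    nodes[[id]]$children <- c(left_id, right_id)
    n_splits <- n_splits + 1L
  }
  nodes <- lapply(nodes, function(nd) { nd$rows <- NULL; nd })
  structure(list(nodes = nodes, outcome = outcome, features = features,
                 positive = positive, criterion = criterion,
                 n_splits = n_splits, policy = NULL),
            class = "cart_tree")
}

route_case <- function(tree, row) {
  id <- 1L
  repeat {
    nd <- tree$nodes[[id]]
    if (nd$terminal) return(id)
    x <- row[[nd$split$variable]]
    left <- if (nd$split$type == "numeric") {
      as.numeric(x) <= nd$split$threshold
    } else as.character(x) %in% nd$split$left_values
    id <- nd$children[if (left) 1L else 2L]
  }
}

#' Route cases through a tree
#'
#' @param object A `cart_tree`.
#' @param newdata data.frame of cases.
#' @param ... Unused.
#' @return data.frame with `node_id`, posterior `p_autism` (terminal class
#'   fraction), and `decision` when the tree carries a policy.
#' @export
predict.cart_tree <- function(object, newdata, ...) {
  ids <- vapply(seq_len(nrow(newdata)), function(i)
    route_case(object, newdata[i, , drop = FALSE]), 1L)
  post <- vapply(ids, function(id) {
    ct <- object$nodes[[id]]$counts
    if (sum(ct) == 0) 0.5 else unname(ct["autism"] / sum(ct))
  }, 1.0)
  out <- data.frame(node_id = ids, p_autism = post)
  if (!is.null(object$policy))
    out$decision <- unname(object$policy[as.character(ids)])
  out
}

#' Attach a terminal decision policy to a tree
#'
#' @param tree A `cart_tree`.
#' @param policy Named character vector mapping terminal node id to
#'   `"autism"`, `"nonautism"` or `"refer"`; must cover every terminal.
#' @return The tree with the policy attached.
#' @export
set_decision_policy <- function(tree, policy) {
  stopifnot(inherits(tree, "cart_tree"),
            all(policy %in% c("autism", "nonautism", "refer")))
  term <- vapply(tree$nodes, function(nd) nd$terminal, TRUE)
  term_ids <- as.character(which(term))
  if (!setequal(names(policy), term_ids))
    stop("policy must map exactly the terminal nodes: ",
         paste(term_ids, collapse = ", "), call. = FALSE)
  tree$policy <- policy
  tree
}

#' The published integration tree
#'
#' The hard-coded decision tree reported for the 146-child cohort,
#' integrating the composite biomarker (root split), practitioner (EAE Hub)
#' diagnosis, biomarker frequency and diagnostic certainty, with the
#' published node counts (reference autism, nonautism) and the published
#' terminal decisions: diagnose at nodes 6, 9, 10 and 12; rule out at node
#' 5; refer at nodes 8 and 13.
#'
#' Expected feature columns when routing cases: `positive` (logical
#' composite index), `frequency` (0-6), `eae_dx` and `certainty`.
#'
#' @return A `cart_tree` with node ids 1-13 matching the published figure
#'   and an attached decision policy.
#' @export
published_tree <- function() {
  nd <- function(id, a, n, split = NULL, children = NULL) {
    list(id = id, depth = NA_integer_,
         counts = c(autism = a, nonautism = n),
         terminal = is.null(split), split = split, children = children)
  }
  num <- function(v, t) list(variable = v, type = "numeric", threshold = t,
                             label = sprintf("%s<=%g", v, t))
  cat2 <- function(v, lv) list(variable = v, type = "categorical",
                               left_values = lv,
                               label = sprintf("%s=%s", v, lv))
  nodes <- list(
    nd(1L, 102L, 44L, num("positive", 0), c(2L, 3L)),
    nd(2L, 23L, 34L, cat2("eae_dx", "autism"), c(4L, 5L)),
    nd(3L, 79L, 10L, cat2("eae_dx", "autism"), c(6L, 7L)),
    nd(4L, 14L, 8L, cat2("certainty", "uncertain"), c(8L, 9L)),
    nd(5L, 9L, 26L),
    nd(6L, 57L, 0L),
    nd(7L, 22L, 10L, num("frequency", 1), c(11L, 10L)),
    nd(8L, 2L, 5L),
    nd(9L, 12L, 3L),
    nd(10L, 10L, 0L),
    nd(11L, 12L, 10L, cat2("certainty", "uncertain"), c(12L, 13L)),
    nd(12L, 9L, 1L),
    nd(13L, 3L, 9L)
  )
  tree <- structure(list(nodes = nodes, outcome = "group",
                         features = c("positive", "frequency", "eae_dx",
                                      "certainty"),
                         positive = "autism", criterion = "published",
                         n_splits = 6L, policy = NULL),
                    class = "cart_tree")
  set_decision_policy(tree, c(`5` = "nonautism", `6` = "autism",
                              `8` = "refer", `9` = "autism",
                              `10` = "autism", `12` = "autism",
                              `13` = "refer"))
}

#' Evaluate a tree's three-way decisions against reference diagnosis
#'
#' Routes cases to terminals, applies the decision policy, excludes referred
#' cases, and computes [accuracy_stats()] for the diagnose / rule-out
#' decisions against the reference label.
#'
#' @param tree A `cart_tree` with a policy (see [set_decision_policy()]).
#' @param cases data.frame of cases with the tree's feature columns and the
#'   outcome column; omit to evaluate from the node counts stored in the
#'   tree (the published worked example).
#' @return An [accuracy_stats()] with the referred count, or `NULL` if no
#'   case is decided.
#' @export
evaluate_decided <- function(tree, cases = NULL) {
  stopifnot(inherits(tree, "cart_tree"))
  if (is.null(tree$policy)) stop("tree carries no decision policy",
                                 call. = FALSE)
  if (is.null(cases)) {
    tp <- fp <- fn <- tn <- referred <- 0L
    for (id in names(tree$policy)) {
      ct <- tree$nodes[[as.integer(id)]]$counts
      dec <- tree$policy[[id]]
      if (dec == "autism") { tp <- tp + ct[["autism"]]
                             fp <- fp + ct[["nonautism"]] }
      else if (dec == "nonautism") { fn <- fn + ct[["autism"]]
                                     tn <- tn + ct[["nonautism"]] }
      else referred <- referred + sum(ct)
    }
    if (tp + fp + fn + tn == 0) return(NULL)
    return(accuracy_stats(tp = tp, fp = fp, fn = fn, tn = tn,
                          referred = referred))
  }
  pred <- predict(tree, cases)
  y <- cases[[tree$outcome]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == tree$positive
  decided <- pred$decision != "refer"
  if (!any(decided)) return(NULL)
  accuracy_stats(confusion_2x2(pred$decision[decided] == "autism",
                               y[decided]),
                 referred = sum(!decided))
}

tree_structure_signature <- function(tree) {
  labs <- vapply(tree$nodes, function(nd)
    if (nd$terminal) NA_character_ else nd$split$label, "")
  paste(labs[!is.na(labs)], collapse = " | ")
}

#' Stratified k-fold cross-validation of the tree
#'
#' Splits the cases into k folds stratified by outcome, refits the tree on
#' each training set, and records the selected structure plus training and
#' validation AUCs of the terminal-posterior scores.
#'
#' @inheritParams fit_cart
#' @param k Number of folds (>= 2).
#' @param seed Seed for the fold assignment.
#' @param ... Passed to [fit_cart()].
#' @return Object of class `cv_report`: per-fold data.frame (`fold`,
#'   `structure`, `train_auc`, `valid_auc`), `modal_structure`,
#'   `modal_count`, `mean_train_auc`, `mean_valid_auc`, `seed`.
#' @export
cross_validate <- function(data, outcome, features, k = 5L, seed = 1L,
                           ...) {
  stopifnot(k >= 2)
  y <- data[[outcome]]
  if (is.character(y) || is.factor(y)) y <- as.character(y) == "autism"
  if (min(sum(y), sum(!y)) < k)
    stop("each class needs at least k cases for stratified folds",
         call. = FALSE)
  folds <- with_seed(seed, {
    f <- integer(nrow(data))
    for (cls in c(TRUE, FALSE)) {
      idx <- sample(which(y == cls))
      f[idx] <- rep_len(seq_len(k), length(idx))
    }
    f
  })
  rows <- lapply(seq_len(k), function(fold) {
    train <- data[folds != fold, , drop = FALSE]
    test <- data[folds == fold, , drop = FALSE]
    fit <- fit_cart(train, outcome, features, ...)
    ytr <- train[[outcome]]; yte <- test[[outcome]]
    if (is.character(ytr)) { ytr <- ytr == "autism"; yte <- yte == "autism" }
    data.frame(fold = fold,
               structure = tree_structure_signature(fit),
               train_auc = roc_auc(predict(fit, train)$p_autism, ytr),
               valid_auc = roc_auc(predict(fit, test)$p_autism, yte))
  })
  per_fold <- do.call(rbind, rows)
  tab <- table(per_fold$structure)
  structure(list(per_fold = per_fold,
                 modal_structure = names(tab)[which.max(tab)],
                 modal_count = as.integer(max(tab)),
                 mean_train_auc = mean(per_fold$train_auc),
                 mean_valid_auc = mean(per_fold$valid_auc),
                 k = k, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d): modal structure in %d/%d folds\n",
              x$k, x$seed, x$modal_count, x$k))
  cat("  modal:", x$modal_structure, "\n")
  cat(sprintf("  mean AUC: training %.3f, validation %.3f\n",
              x$mean_train_auc, x$mean_valid_auc))
  invisible(x)
}

#' @export
print.cart_tree <- function(x, ...) {
  cat("Classification tree (", x$criterion, ", ", x$n_splits, " splits)\n",
      sep = "")
  rec <- function(id, indent) {
    nd <- x$nodes[[id]]
    ct <- nd$counts
    dec <- if (nd$terminal && !is.null(x$policy))
      paste0("  -> ", x$policy[[as.character(id)]]) else ""
    cat(strrep("  ", indent),
        sprintf("node %d [%d autism / %d nonautism]%s\n", id,
                ct[["autism"]], ct[["nonautism"]], dec), sep = "")
    if (!nd$terminal) {
      cat(strrep("  ", indent + 1), "split: ", nd$split$label, "\n", sep = "")
      rec(nd$children[1], indent + 1)
      rec(nd$children[2], indent + 1)
    }
  }
  rec(1L, 0)
  invisible(x)
}

#' Serialize a tree (nodes, rules, counts, decisions) to JSON
#'
#' @param tree A `cart_tree`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd) {
    out <- list(id = nd$id, counts = as.list(nd$counts),
                terminal = nd$terminal)
    if (!nd$terminal) {
      out$split <- nd$split[setdiff(names(nd$split), "gain")]
      out$children <- nd$children
    } else if (!is.null(tree$policy)) {
      out$decision <- tree$policy[[as.character(nd$id)]]
    }
    out
  })
  jsonlite::write_json(list(outcome = tree$outcome,
                            features = tree$features,
                            criterion = tree$criterion,
                            n_splits = tree$n_splits,
                            nodes = nodes),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
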