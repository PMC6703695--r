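# Segmentation benchmarking: instance matching, error taxonomy and
# precision/recall/F-measure against a ground-truth label image.
#
# Matching rule (mutual majority): a GT-test pair is a candidate match
# when their overlap exceeds half of each instance's volume. A GT
# instance is then
#   merge member - its majority cover is a test instance that is also the
#                  majority cover of another GT instance;
#   split parent - it majority-covers two or more test instances;
#   accurate     - it has exactly one mutual candidate and no conflict;
#   miss         - otherwise.
# Test instances not matched by any of those are spurious. A Jaccard
# dialect (candidate match when JI >= cut) is selectable.

#' Match GT and test instances and classify errors
#'
#' @param gt,test [label_volume()]s on the same grid.
#' @param rule `"majority"` (default) or `"jaccard"`.
#' @param cut majority fraction or JI cut, default 0.5.
#' @return object of class `MatchTable`: data.frames `gt` (`id`, `class`,
#'   `partner`, `ji`) and `test` (`id`, `class`, `partner`), plus counts.
#' @export
match_instances <- function(gt, test, rule = c("majority", "jaccard"), cut = 0.5) {
  rule <- match.arg(rule)
  if (!identical(dim(gt$data), dim(test$data)))
    stopf("nucridge_grid_mismatch", "GT and test grids differ")
  gv <- as.vector(gt$data); tv <- as.vector(test$data)
  keep <- gv > 0L | tv > 0L
  gv <- gv[keep]; tv <- tv[keep]
  gids <- sort(setdiff(unique(gv), 0L)); tids <- sort(setdiff(unique(tv), 0L))
  gsize <- table(factor(gv[gv > 0L], gids))
  tsize <- table(factor(tv[tv > 0L], tids))
  both <- gv > 0L & tv > 0L
  ov <- table(factor(gv[both], gids), factor(tv[both], tids))
  classify_matches(gids, tids, as.numeric(gsize), as.numeric(tsize),
                   matrix(as.numeric(ov), length(gids), length(tids)),
                   rule, cut)
}

# Core classification from sizes and the overlap matrix; shared by the
# table-based path and usable directly on toy inputs.
classify_matches <- function(gids, tids, gsize, tsize, ov, rule = "majority",
                             cut = 0.5) {
  ng <- length(gids); nt <- length(tids)
  gclass <- rep("miss", ng); gpartner <- rep(NA_integer_, ng); gji <- rep(NA_real_, ng)
  tclass <- rep("spurious", nt); tpartner <- rep(NA_integer_, nt)
  if (ng && nt) {
    ji <- ov / (outer(gsize, tsize, "+") - ov)
    if (rule == "majority") {
      cover_g <- ov > cut * gsize            # [g, t]: t covers most of g
      cover_t <- ov > matrix(cut * tsize, ng, nt, byrow = TRUE)  # g covers most of t
    } else {
      cover_g <- cover_t <- ji >= cut
    }
    maj_of_g <- apply(cover_g, 1L, function(r) if (any(r)) which(r)[1L] else NA_integer_)
    # merge: several GT sharing one majority test instance
    tt <- table(maj_of_g[!is.na(maj_of_g)])
    merge_targets <- as.integer(names(tt)[tt >= 2L])
    for (g in seq_len(ng)) {
      t_ <- maj_of_g[g]
      n_cov <- sum(cover_t[g, ])
      if (!is.na(t_) && t_ %in% merge_targets) {
        gclass[g] <- "merge"; gpartner[g] <- tids[t_]; gji[g] <- ji[g, t_]
      } else if (n_cov >= 2L) {
        gclass[g] <- "split"
      } else if (!is.na(t_) && cover_t[g, t_]) {
        gclass[g] <- "accurate"; gpartner[g] <- tids[t_]; gji[g] <- ji[g, t_]
        tclass[t_] <- "accurate"; tpartner[t_] <- gids[g]
      }
    }
    for (t_ in merge_targets) { tclass[t_] <- "merge" }
    for (g in which(gclass == "split")) {
      prods <- which(cover_t[g, ] & tclass == "spurious")
      tclass[prods] <- "split"; tpartner[prods] <- gids[g]
    }
  }
  structure(list(
    gt = data.frame(id = gids, class = gclass, partner = gpartner, ji = gji),
    test = data.frame(id = tids, class = tclass, partner = tpartner),
    rule = rule, cut = cut), class = "MatchTable")
}

#' Precision, recall and F-measure from a match table
#'
#' Precision is the fraction of test instances that are accurate hits
#' (each test instance counted once whatever its class); recall the
#' fraction of GT instances accurately found; F their harmonic mean
#' (0 when both are 0). With an empty GT, recall and F are `NaN` and a
#' warning is raised.
#'
#' @param table a `MatchTable`.
#' @return object of class `BenchmarkReport`: named list with `counts`
#'   (accurate, merge, miss, split, spurious over GT/test as
#'   appropriate), `precision`, `recall`, `f_measure`, `mean_ji`.
#' @export
compute_metrics <- function(table) {
  gcl <- table$gt$class; tcl <- table$test$class
  acc <- sum(gcl == "accurate")
  counts <- c(accurate = acc,
              merge = sum(gcl == "merge"),
              miss = sum(gcl == "miss"),
              split = sum(gcl == "split"),
              spurious = sum(tcl == "spurious"))
  nt <- nrow(table$test); ng <- nrow(table$gt)
  precision <- if (nt > 0L) acc / nt else NaN
  if (ng == 0L) {
    warnf("empty ground truth: recall undefined")
    recall <- NaN
  } else recall <- acc / ng
  f <- if (is.nan(precision) || is.nan(recall)) NaN
    else if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  structure(list(counts = counts, n_gt = ng, n_test = nt,
                 precision = precision, recall = recall, f_measure = f,
                 mean_ji = mean(table$gt$ji[gcl == "accurate"])),
            class = "BenchmarkReport")
}

#' @export
print.BenchmarkReport <- function(x, ...) {
  cat(sprintf("BenchmarkReport: %d GT / %d test instances\n", x$n_gt, x$n_test))
  cat("  ", paste(names(x$counts), x$counts, sep = "=", collapse = " "), "\n")
  cat(sprintf("  precision=%.4f recall=%.4f F=%.4f mean JI(accurate)=%.4f\n",
              x$precision, x$recall, x$f_measure, x$mean_ji))
  invisible(x)
}

#' Benchmark a segmentation against ground truth
#'
#' Convenience wrapper: [match_instances()] + [compute_metrics()].
#' @inheritParams match_instances
#' @return a `BenchmarkReport` with the `MatchTable` attached as
#'   `$match`.
#' @export
benchmark_segmentation <- function(gt, test, rule = "majority", cut = 0.5) {
  m <- match_instances(gt, test, rule, cut)
  rep <- compute_metrics(m)
  rep$match <- m
  rep
}

ERROR_CODES <- c(accurate = 1L, merge = 2L, split = 3L, spurious = 4L, miss = 5L)

#' Write a colour-coded 3D error map
#'
#' A label image whose voxels carry the error class of their instance:
#' 1 accurate, 2 merge, 3 split, 4 spurious (test-side classes, rendered
#' from the test masks) and 5 miss (rendered from the GT masks). A text
#' sidecar records the legend.
#'
#' @param table a `MatchTable`.
#' @param gt,test the two [label_volume()]s.
#' @param path output TIFF path; the legend goes to `paste0(path,
#'   ".legend.txt")`.
#' @return `path`, invisibly.
#' @export
write_error_map <- function(table, gt, test, path) {
  map <- array(0L, dim(test$data))
  code_of_t <- ERROR_CODES[table$test$class]
  for (i in seq_len(nrow(table$test)))
    map[test$data == table$test$id[i]] <- code_of_t[i]
  for (i in which(table$gt$class == "miss"))
    map[gt$data == table$gt$id[i] & map == 0L] <- ERROR_CODES[["miss"]]
  write_label_volume(label_volume(map, gt$calibration), path)
  writeLines(c("code\tclass", sprintf("%d\t%s", ERROR_CODES, names(ERROR_CODES))),
             paste0(path, ".legend.txt"))
  invisible(path)
}

#' Batch benchmark: directories of GT and test images matched by name
#'
#' @param gt_dir,test_dir directories of TIFF label images with matching
#'   filenames.
#' @param out_dir output directory: `Summary.tsv` plus one error-map
#'   TIFF per image.
#' @param rule,cut matching dialect, as [match_instances()].
#' @return the summary data.frame, invisibly.
#' @export
benchmark_batch <- function(gt_dir, test_dir, out_dir, rule = "majority", cut = 0.5) {
  files <- intersect(dir(gt_dir, pattern = "\\.tiff?$"), dir(test_dir, pattern = "\\.tiff?$"))
  if (!length(files)) stopf("nucridge_missing_file", "no matching image pairs")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (f in files) {
    gt <- read_label_volume(file.path(gt_dir, f))
    te <- read_label_volume(file.path(test_dir, f))
    m <- match_instances(gt, te, rule, cut)
    rep <- compute_metrics(m)
    write_error_map(m, gt, te, file.path(out_dir, paste0("errormap_", f)))
    rows[[f]] <- data.frame(image = f, n_gt = rep$n_gt, n_test = rep$n_test,
                            t(rep$counts), precision = rep$precision,
                            recall = rep$recall, f_measure = rep$f_measure,
                            mean_ji = rep$mean_ji)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, file.path(out_dir, "Summary.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(df)
}
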