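#' Training configuration
#'
#' Collects every knob of the joint autoencoder / transport optimization.
#' The total objective is \eqn{L = (1-\gamma) L_{recon} + \gamma L_{UOT}}
#' with \eqn{\gamma = 0.2} by default; the transport plan is re-solved from
#' the current embeddings every \code{planRefreshEvery} epochs and held
#' fixed in between (its gradient flows only through the cost). The first
#' \code{warmupEpochs} epochs train the reconstruction alone.
#'
#' @param gamma trade-off in [0, 1] between reconstruction and transport
#'   loss (default 0.2).
#' @param epochs total full-batch gradient epochs.
#' @param lr Adam learning rate.
#' @param planRefreshEvery epochs between transport plan re-solves.
#' @param warmupEpochs reconstruction-only epochs at the start.
#' @param seed integer governing parameter initialization (and any
#'   sampling).
#' @param epsilon,rho1,rho2 transport parameters; \code{partial = TRUE} is a
#'   shorthand for the partial-alignment regime rho1 = Inf, rho2 = 0.01.
#' @param uotNOuter,uotNInner,uotTol solver budget used during training
#'   refreshes (the final plan is re-solved at \code{finalNOuter}).
#' @param finalNOuter outer iterations for the final plan.
#' @param hiddenDims encoder widths after the input layer.
#' @param activation,gateActivation autoencoder nonlinearities.
#' @param costSquared use squared latent distance as transport cost.
#' @param spatialInit initialize the plan from a kernel on centered,
#'   per-slice-normalized coordinates instead of the uniform plan.
#' @param partial logical shorthand, see above.
#' @param fineTuneEpochs reconstruction-only adaptation epochs used by
#'   [integrateNewSlice()] (0 = frozen model).
#' @param referenceId slice id used as reference template in multi-slice
#'   integration.
#' @return a validated configuration list of class "sliceotConfig".
#' @export
trainConfig <- function(gamma = 0.2, epochs = 500L, lr = 1e-3,
                        planRefreshEvery = 10L, warmupEpochs = 100L,
                        seed = 0L, epsilon = 0.05, rho1 = 1, rho2 = 1,
                        uotNOuter = 10L, uotNInner = 10L, uotTol = 1e-6,
                        finalNOuter = 50L, hiddenDims = c(512, 30),
                        activation = "elu", gateActivation = "sigmoid",
                        costSquared = FALSE, spatialInit = FALSE,
                        partial = FALSE, fineTuneEpochs = 50L,
                        referenceId = NULL) {
    if (partial) { rho1 <- Inf; rho2 <- 0.01 }
    cfg <- list(gamma = gamma, epochs = as.integer(epochs), lr = lr,
                planRefreshEvery = as.integer(planRefreshEvery),
                warmupEpochs = as.integer(warmupEpochs),
                seed = as.integer(seed), epsilon = epsilon, rho1 = rho1,
                rho2 = rho2, uotNOuter = as.integer(uotNOuter),
                uotNInner = as.integer(uotNInner), uotTol = uotTol,
                finalNOuter = as.integer(finalNOuter),
                hiddenDims = as.integer(hiddenDims),
                activation = activation, gateActivation = gateActivation,
                costSquared = costSquared, spatialInit = spatialInit,
                fineTuneEpochs = as.integer(fineTuneEpochs),
                referenceId = referenceId)
    if (cfg$gamma < 0 || cfg$gamma > 1)
        stop("parameter error: gamma must lie in [0, 1]")
    if (cfg$epochs < 1L) stop("parameter error: epochs must be >= 1")
    if (cfg$lr <= 0) stop("parameter error: lr must be positive")
    if (cfg$planRefreshEvery < 1L)
        stop("parameter error: planRefreshEvery must be >= 1")
    if (cfg$warmupEpochs < 0L)
        stop("parameter error: warmupEpochs must be >= 0")
    class(cfg) <- "sliceotConfig"
    cfg
}

.adam_init <- function(theta) {
    list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}
.adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
    state$t <- state$t + 1L
    state$m <- beta1 * state$m + (1 - beta1) * grad
    state$v <- beta2 * state$v + (1 - beta2) * grad^2
    mhat <- state$m / (1 - beta1^state$t)
    vhat <- state$v / (1 - beta2^state$t)
    list(state = state, theta = theta - lr * mhat / (sqrt(vhat) + eps))
}

.flatten_grads <- function(g) unlist(c(g$W, g$vs, g$vr), use.names = FALSE)

# spatially informed initial plan: Gaussian kernel on centered,
# per-slice scale-normalized coordinates
.spatial_plan_init <- function(coordsX, coordsY) {
    norm01 <- function(M) {
        M <- sweep(M, 2L, colMeans(M))
        s <- sqrt(mean(rowSums(M^2)))
        if (s > 0) M / s else M
    }
    X <- norm01(as.matrix(coordsX)); Y <- norm01(as.matrix(coordsY))
    D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * X %*% t(Y)
    Km <- exp(-pmax(D2, 0) / 0.5)
    Km / sum(Km)
}

#' Jointly train the autoencoder and transport plan for a slice pair
#'
#' Alternating optimization: full-batch Adam on the tied-weight graph
#' attention autoencoder under \eqn{(1-\gamma) L_{recon} + \gamma L_{UOT}},
#' with the unbalanced transport plan re-solved from the current latent
#' cost every \code{planRefreshEvery} epochs (warm-started from the previous
#' plan) and treated as a constant in between. Warmup epochs use
#' \eqn{\gamma = 0}. With \code{gamma = 0} this reduces exactly to
#' autoencoder training and the plan is computed once post hoc.
#' Deterministic given \code{config$seed}.
#'
#' @param sliceX,sliceY \linkS4class{STSlice}s sharing an identical ordered
#'   gene list (see [normalizeAndIntersect()]).
#' @param graphX,graphY \linkS4class{SpatialGraph}s; built automatically
#'   (default radius heuristic) when NULL.
#' @param config a [trainConfig()].
#' @return an \linkS4class{IntegrationResult}.
#' @export
trainPair <- function(sliceX, sliceY, graphX = NULL, graphY = NULL,
                      config = trainConfig()) {
    if (!identical(rownames(sliceX), rownames(sliceY)))
        stop("slices must share an identical ordered gene list; ",
             "run normalizeAndIntersect() first")
    if (is.null(graphX)) graphX <- buildSpatialGraph(sliceX)
    if (is.null(graphY)) graphY <- buildSpatialGraph(sliceY)
    Hx <- spotExpr(sliceX); Hy <- spotExpr(sliceY)
    H0 <- rbind(Hx, Hy)
    nx <- nrow(Hx); n <- nrow(H0)
    edges <- .as_edge_list(list(graphX, graphY))
    model <- initGATModel(ncol(H0), config$hiddenDims,
                          activation = config$activation,
                          gateActivation = config$gateActivation,
                          seed = config$seed)
    theta <- .flatten_params(model)
    adam <- .adam_init(theta)
    history <- data.frame(epoch = integer(0), lossRecon = numeric(0),
                          lossUOT = numeric(0), lossTotal = numeric(0))
    plan <- NULL
    solveFromZ <- function(z, tInit, nOuter) {
        zx <- z[seq_len(nx), , drop = FALSE]
        zy <- z[(nx + 1L):n, , drop = FALSE]
        C <- latentCost(zx, zy, squared = config$costSquared,
                        normalize = TRUE)
        solveUOT(C, epsilon = config$epsilon, rho1 = config$rho1,
                 rho2 = config$rho2, tInit = tInit, nOuter = nOuter,
                 nInner = config$uotNInner, tol = config$uotTol)
    }
    tInit0 <- if (config$spatialInit)
        .spatial_plan_init(spatialCoords(sliceX), spatialCoords(sliceY))
    else NULL
    for (epoch in seq_len(config$epochs)) {
        inWarmup <- epoch <= config$warmupEpochs || config$gamma == 0
        gammaE <- if (inWarmup) 0 else config$gamma
        if (!inWarmup) {
            k <- epoch - config$warmupEpochs - 1L
            if (k %% config$planRefreshEvery == 0L || is.null(plan)) {
                fwz <- .gat_loss_grad(model, H0, edges, nx,
                                      wantGrads = FALSE)
                plan <- solveFromZ(fwz$z, tInit0, config$uotNOuter)
            }
        }
        lg <- .gat_loss_grad(model, H0, edges, nx,
                             plan = if (inWarmup) NULL else plan,
                             gamma = gammaE,
                             costSquared = config$costSquared)
        if (!is.finite(lg$loss))
            stop(sprintf(
                "non-finite loss at epoch %d (recon %.4g, uot %.4g)",
                epoch, lg$lossRecon, lg$lossUOT))
        st <- .adam_step(adam, theta, .flatten_grads(lg$grads), config$lr)
        adam <- st$state; theta <- st$theta
        model <- .unflatten_params(model, theta)
        history[epoch, ] <- list(epoch, lg$lossRecon, lg$lossUOT,
                                 (1 - gammaE) * lg$lossRecon +
                                     gammaE * lg$lossUOT)
    }
    fwz <- .gat_loss_grad(model, H0, edges, nx, wantGrads = FALSE)
    plan <- solveFromZ(fwz$z, tInit0, config$finalNOuter)
    ids <- factor(rep(c(sliceId(sliceX), sliceId(sliceY)), c(nx, n - nx)),
                  levels = c(sliceId(sliceX), sliceId(sliceY)))
    new("IntegrationResult", embedding = unname(fwz$z), sliceIds = ids,
        plan = plan, model = model, history = history,
        config = unclass(config))
}

#' Integrate a new slice using a trained reference model
#'
#' Treats a trained autoencoder as a reference model: the new slice is
#' (optionally) fine-tuned for a few reconstruction-only epochs on its own
#' graph, encoded into the common latent space, and coupled to a designated
#' reference slice by an unbalanced transport plan. No joint retraining
#' takes place; with \code{fineTuneEpochs = 0} the model is used frozen.
#'
#' @param existing an \linkS4class{IntegrationResult} from [trainPair()] or
#'   a previous integration.
#' @param newSlice \linkS4class{STSlice} sharing the trained gene list.
#' @param newGraph its \linkS4class{SpatialGraph} (built if NULL).
#' @param referenceId which existing slice the plan couples to; default the
#'   first slice of \code{existing}.
#' @param config a [trainConfig()]; \code{fineTuneEpochs} and the transport
#'   parameters are honored, other training knobs are ignored.
#' @return an \linkS4class{IntegrationResult} whose embedding has the new
#'   slice's rows appended and whose plan couples newSlice -> reference.
#' @export
integrateNewSlice <- function(existing, newSlice, newGraph = NULL,
                              referenceId = NULL, config = trainConfig()) {
    model <- existing@model
    g <- model@layerDims[1L]
    Hn <- spotExpr(newSlice)
    if (ncol(Hn) != g)
        stop("gene-list mismatch: new slice has ", ncol(Hn),
             " genes, model expects ", g)
    if (is.null(newGraph)) newGraph <- buildSpatialGraph(newSlice)
    edges <- .as_edge_list(list(newGraph))
    if (config$fineTuneEpochs > 0L) {
        theta <- .flatten_params(model)
        adam <- .adam_init(theta)
        for (epoch in seq_len(config$fineTuneEpochs)) {
            lg <- .gat_loss_grad(model, Hn, edges, nrow(Hn))
            st <- .adam_step(adam, theta, .flatten_grads(lg$grads),
                             config$lr)
            adam <- st$state; theta <- st$theta
            model <- .unflatten_params(model, theta)
        }
    }
    zNew <- unname(gatEncode(model, Hn, newGraph))
    attr(zNew, "forwardCache") <- NULL
    if (is.null(referenceId)) referenceId <- config$referenceId
    if (is.null(referenceId)) referenceId <- levels(existing@sliceIds)[1L]
    if (!referenceId %in% levels(existing@sliceIds))
        stop("reference slice '", referenceId, "' not present in the ",
             "existing integration")
    zRef <- existing@embedding[existing@sliceIds == referenceId, ,
                               drop = FALSE]
    C <- latentCost(zNew, zRef, squared = config$costSquared,
                    normalize = TRUE)
    plan <- solveUOT(C, epsilon = config$epsilon, rho1 = config$rho1,
                     rho2 = config$rho2, nOuter = config$finalNOuter,
                     nInner = config$uotNInner, tol = config$uotTol)
    ids <- factor(c(as.character(existing@sliceIds),
                    rep(sliceId(newSlice), nrow(zNew))),
                  levels = c(levels(existing@sliceIds), sliceId(newSlice)))
    new("IntegrationResult",
        embedding = rbind(existing@embedding, zNew), sliceIds = ids,
        plan = plan, model = model, history = existing@history,
        config = unclass(config))
}

#' @rdname IntegrationResult-accessors
#' @export
setGeneric("embedding", function(x) standardGeneric("embedding"))
#' @rdname IntegrationResult-accessors
#' @export
setGeneric("trainingHistory", function(x) standardGeneric("trainingHistory"))
#' @rdname IntegrationResult-accessors
#' @export
setGeneric("transportPlan", function(x) standardGeneric("transportPlan"))
#' @rdname IntegrationResult-accessors
#' @export
setGeneric("trainedModel", function(x) standardGeneric("trainedModel"))
#' @rdname IntegrationResult-accessors
#' @export
setGeneric("sliceIds", function(x) standardGeneric("sliceIds"))

#' Accessors for IntegrationResult
#'
#' @param x an \linkS4class{IntegrationResult}.
#' @name IntegrationResult-accessors
NULL

#' @rdname IntegrationResult-accessors
#' @export
setMethod("embedding", "IntegrationResult", function(x) x@embedding)
#' @rdname IntegrationResult-accessors
#' @export
setMethod("trainingHistory", "IntegrationResult", function(x) x@history)
#' @rdname IntegrationResult-accessors
#' @export
setMethod("transportPlan", "IntegrationResult", function(x) x@plan)
#' @rdname IntegrationResult-accessors
#' @export
setMethod("trainedModel", "IntegrationResult", function(x) x@model)
#' @rdname IntegrationResult-accessors
#' @export
setMethod("sliceIds", "IntegrationResult", function(x) x@sliceIds)

#' @export
setMethod("show", "IntegrationResult", function(object) {
    tab <- table(object@sliceIds)
    cat(sprintf("IntegrationResult: %d spots (%s), latent dim %d\n",
                nrow(object@embedding),
                paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
                ncol(object@embedding)))
    if (nrow(object@history))
        cat(sprintf("  final losses: recon %.4g, uot %.4g\n",
                    utils::tail(object@history$lossRecon, 1),
                    utils::tail(object@history$lossUOT, 1)))
})

#' Save / load a model checkpoint
#'
#' Plain-text (YAML) serialization of the autoencoder parameters,
#' architecture and activations.
#' @param model a \linkS4class{GATModel}.
#' @param path output file.
#' @export
saveCheckpoint <- function(model, path) {
    obj <- list(layerDims = model@layerDims,
                activation = model@activation,
                gateActivation = model@gateActivation,
                seed = model@seed,
                theta = .flatten_params(model))
    yaml::write_yaml(obj, path, precision = 17L)
    invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
    obj <- yaml::read_yaml(path)
    model <- initGATModel(obj$layerDims[1L], obj$layerDims[-1L],
                          activation = obj$activation,
                          gateActivation = obj$gateActivation,
                          seed = obj$seed)
    .unflatten_params(model, as.numeric(obj$theta))
}
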