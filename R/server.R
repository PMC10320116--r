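# HTTP surface over the query functions. Metadata and errors travel as
# JSON; data responses as BinaryCIF bodies. Routes:
#   GET /v1/{source}/{id}/metadata
#   GET /v1/{source}/{id}/volume/box/{x0},{y0},{z0}/{x1},{y1},{z1}?max_points=N
#   GET /v1/{source}/{id}/segmentation/{lattice_id}/box/...?max_points=N
#   GET /v1/{source}/{id}/mesh

.DEFAULT_MAX_POINTS <- 1e6

.errorCode <- function(msg) {
  codes <- c("not found" = 404L, "empty region" = 400L,
             "invalid budget" = 400L, "entry exists" = 409L)
  for (k in names(codes)) if (startsWith(msg, k)) return(codes[[k]])
  500L
}

.jsonResponse <- function(status, obj) {
  list(status = status,
       headers = list("Content-Type" = "application/json"),
       body = as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                            digits = I(17), null = "null")))
}

.parseTriple <- function(s) {
  p <- suppressWarnings(as.integer(strsplit(s, ",", fixed = TRUE)[[1]]))
  if (length(p) != 3L || any(is.na(p))) stopf("empty region: malformed box '%s'", s)
  p
}

# Pure request handler (method, path, query string) -> httpuv response
# list; exercised directly by tests without a socket.
.handleRequest <- function(root, method, path, query = "") {
  tryCatch({
    if (method != "GET") return(.jsonResponse(405L, list(error = "method not allowed")))
    parts <- strsplit(sub("^/", "", path), "/", fixed = TRUE)[[1]]
    if (length(parts) < 2L || parts[1] != "v1")
      return(.jsonResponse(404L, list(error = "no such route")))
    if (length(parts) == 2L && parts[2] == "entries") {
      return(.jsonResponse(200L, listEntries(root)))
    }
    if (length(parts) < 4L) return(.jsonResponse(404L, list(error = "no such route")))
    source <- parts[2]; id <- parts[3]
    q <- list()
    if (nzchar(query)) {
      for (kv in strsplit(strsplit(sub("^\\?", "", query), "&")[[1]], "=")) {
        if (length(kv) == 2L) q[[kv[1]]] <- kv[2]
      }
    }
    maxPoints <- as.numeric(q[["max_points"]] %||% .DEFAULT_MAX_POINTS)
    bcifBody <- function(bytes)
      list(status = 200L,
           headers = list("Content-Type" = "application/octet-stream"),
           body = bytes)
    if (parts[4] == "metadata") {
      md <- getMetadata(source, id, root)
      return(.jsonResponse(200L, md))
    }
    if (parts[4] == "mesh") {
      mp <- queryMeshes(source, id, root)
      md <- getMetadata(source, id, root)
      return(bcifBody(buildResponse(mp, md$metadata, md$annotations)))
    }
    if (parts[4] == "volume" && length(parts) == 7L && parts[5] == "box") {
      md <- getMetadata(source, id, root)
      qq <- BoxQuery(source, id, "volume", .parseTriple(parts[6]),
                     .parseTriple(parts[7]), maxPoints)
      return(bcifBody(buildResponse(queryBox(qq, root), md$metadata,
                                    md$annotations)))
    }
    if (parts[4] == "segmentation" && length(parts) == 8L && parts[6] == "box") {
      md <- getMetadata(source, id, root)
      qq <- BoxQuery(source, id, "lattice", .parseTriple(parts[7]),
                     .parseTriple(parts[8]), maxPoints,
                     latticeId = as.integer(parts[5]))
      return(bcifBody(buildResponse(queryBox(qq, root), md$metadata,
                                    md$annotations)))
    }
    .jsonResponse(404L, list(error = "no such route"))
  }, error = function(e) {
    msg <- conditionMessage(e)
    .jsonResponse(.errorCode(msg), list(error = msg))
  })
}

#' Serve a database root over HTTP
#'
#' Starts a blocking HTTP service (requires the httpuv package) exposing
#' metadata as JSON and box/mesh queries as BinaryCIF bodies under
#' `/v1/{source}/{id}/...`. Errors are structured JSON with stable
#' status codes. The default point budget when `max_points` is omitted
#' is 10^6.
#'
#' @param root database root directory.
#' @param port TCP port.
#' @param host bind address.
#' @return does not return; interrupt to stop.
#' @export
serveEntries <- function(root, port = 9999L, host = "127.0.0.1") {
  if (!requireNamespace("httpuv", quietly = TRUE))
    stopf("serveEntries requires the httpuv package")
  app <- list(call = function(req) {
    .handleRequest(root, req$REQUEST_METHOD, req$PATH_INFO,
                   req$QUERY_STRING %||% "")
  })
  message(sprintf("serving %s on http://%s:%d/v1/ (interrupt to stop)",
                  root, host, port))
  httpuv::runServer(host, port, app)
}
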