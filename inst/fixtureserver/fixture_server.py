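#!/usr/bin/env python
"""Loopback HTTP endpoint serving a written fixture directory.

Standard-library only. Routes:
  GET  /ping                     -> {"ok": true} (liveness, unauthenticated)
  POST /auth                     -> body {"token": t}; 200 {"session_id": s} or 401
  GET  /patients/<id>/checks     -> array of check summaries (may be empty)
  GET  /checks/<check_id>        -> full check document, 404 if unknown
Authenticated routes require header X-Session with the issued session id.
"""
import argparse
import json
import os
import sys
from http.server import BaseHTTPRequestHandler, HTTPServer


def main():
    ap = argparse.ArgumentParser()
    ap.add_argument("--dir", required=True)
    ap.add_argument("--port", type=int, required=True)
    ap.add_argument("--host", default="127.0.0.1")
    args = ap.parse_args()

    with open(os.path.join(args.dir, "index.json")) as fh:
        index = json.load(fh)
    token = index["token"]
    session_id = "sess-" + format(abs(hash(token)) % 10**8, "08d")
    checks_dir = os.path.join(args.dir, "checks")

    class Handler(BaseHTTPRequestHandler):
        def log_message(self, *a):
            pass

        def _send(self, code, obj):
            body = json.dumps(obj).encode()
            self.send_response(code)
            self.send_header("Content-Type", "application/json")
            self.send_header("Content-Length", str(len(body)))
            self.end_headers()
            self.wfile.write(body)

        def _authed(self):
            return self.headers.get("X-Session") == session_id

        def do_POST(self):
            if self.path != "/auth":
                return self._send(404, {"error": "not found"})
            n = int(self.headers.get("Content-Length", 0))
            try:
                payload = json.loads(self.rfile.read(n) or b"{}")
            except ValueError:
                return self._send(400, {"error": "bad request body"})
            if payload.get("token") != token:
                return self._send(401, {"error": "invalid token"})
            self._send(200, {"session_id": session_id})

        def do_GET(self):
            parts = [p for p in self.path.split("/") if p]
            if parts == ["ping"]:
                return self._send(200, {"ok": True})
            if not self._authed():
                return self._send(401, {"error": "missing or invalid session"})
            if len(parts) == 3 and parts[0] == "patients" and parts[2] == "checks":
                return self._send(200, index["patients"].get(parts[1], []))
            if len(parts) == 2 and parts[0] == "checks":
                path = os.path.join(checks_dir, parts[1] + ".json")
                if not os.path.isfile(path) or "/" in parts[1] or ".." in parts[1]:
                    return self._send(404, {"error": "check not found"})
                with open(path) as fh:
                    return self._send(200, json.load(fh))
            self._send(404, {"error": "not found"})

    try:
        server = HTTPServer((args.host, args.port), Handler)
    except OSError as exc:
        sys.stderr.write("port in use or unavailable: %s\n" % exc)
        sys.exit(2)
    server.serve_forever()


if __name__ == "__main__":
    main()
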