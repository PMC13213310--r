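"""Batch UMAP embedding helper.

Reads a JSON job description, embeds every input matrix with every requested
random seed using umap-learn, and writes one coordinate CSV per
(matrix, seed). Batching many embeddings into one process amortizes the
numba JIT cost of importing umap.

Job JSON schema:
  {
    "n_neighbors": 15, "min_dist": 0.1, "n_components": 2,
    "init": "spectral", "seeds": [42, 43, ...],
    "inputs": [{"id": "m1", "path": "..."}, ...],
    "out_dir": "..."
  }

Each input path is a headerless CSV matrix (rows = observations). Output
files are <out_dir>/<id>_seed<seed>.csv with x,y per row, full precision.
"""
import json
import os
import sys
import warnings

import numpy as np

warnings.filterwarnings("ignore")

def main(job_path):
    with open(job_path) as fh:
        job = json.load(fh)
    import umap  # deferred: slow import

    for item in job["inputs"]:
        X = np.loadtxt(item["path"], delimiter=",", ndmin=2)
        for seed in job["seeds"]:
            reducer = umap.UMAP(
                n_neighbors=int(job["n_neighbors"]),
                min_dist=float(job["min_dist"]),
                n_components=int(job.get("n_components", 2)),
                init=job.get("init", "spectral"),
                random_state=int(seed),
            )
            coords = reducer.fit_transform(X)
            out = os.path.join(job["out_dir"],
                               "%s_seed%d.csv" % (item["id"], int(seed)))
            np.savetxt(out, coords, delimiter=",", fmt="%.17g")
    print("OK")


if __name__ == "__main__":
    main(sys.argv[1])
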