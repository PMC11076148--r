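"""Bridge between the R package and AnnData h5ad files.

Usage:
    python h5ad_bridge.py export <file.h5ad> <dir>   # h5ad -> X.csv + obs.csv
    python h5ad_bridge.py import <file.h5ad> <dir>   # X.csv (+ obs) -> h5ad

X.csv layout matches the package's csv format: cells as rows, first column
`cell_id`, header = gene names. Annotations travel in obs.csv / X_obs.csv.
"""
import os
import sys

import anndata as ad
import numpy as np
import pandas as pd
import scipy.sparse as sp


def export(h5_path, out_dir):
    adata = ad.read_h5ad(h5_path)
    X = adata.X
    if sp.issparse(X):
        X = X.toarray()
    df = pd.DataFrame(np.asarray(X, dtype=float), columns=list(adata.var_names))
    df.insert(0, "cell_id", list(adata.obs_names))
    df.to_csv(os.path.join(out_dir, "X.csv"), index=False)
    obs = adata.obs.copy()
    obs.insert(0, "cell_id", list(adata.obs_names))
    obs.to_csv(os.path.join(out_dir, "obs.csv"), index=False)


def do_import(h5_path, in_dir):
    df = pd.read_csv(os.path.join(in_dir, "X.csv"))
    cell_ids = df["cell_id"].astype(str).tolist()
    X = df.drop(columns=["cell_id"]).to_numpy(dtype=float)
    var = pd.DataFrame(index=[c for c in df.columns if c != "cell_id"])
    obs = pd.DataFrame(index=cell_ids)
    obs_path = os.path.join(in_dir, "X_obs.csv")
    if os.path.exists(obs_path):
        o = pd.read_csv(obs_path).set_index("cell_id")
        o.index = o.index.astype(str)
        obs = o.loc[cell_ids]
        for col in obs.columns:
            obs[col] = obs[col].astype("category")
    adata = ad.AnnData(X=X, obs=obs, var=var)
    adata.write_h5ad(h5_path)


if __name__ == "__main__":
    cmd, h5, d = sys.argv[1], sys.argv[2], sys.argv[3]
    if cmd == "export":
        export(h5, d)
    elif cmd == "import":
        do_import(h5, d)
    else:
        raise SystemExit(f"unknown command: {cmd}")
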