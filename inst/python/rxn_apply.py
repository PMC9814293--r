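"""Batched structure-rewrite backend for library enumeration.

Reads JSON lines from stdin, one virtual synthesis per line:

    {"id": "p1", "start": "NCCO",
     "steps": [["[C:1](=[O:2])[OX2H1].[NX3;H2:3]>>[C:1](=[O:2])[N:3]",
                "CC(=O)O"], ...]}

Each step is a reaction SMARTS plus an optional building-block SMILES
(null/absent for single-reactant deprotections); the growing design is
always the first component.  Writes one JSON line per input:

    {"id": "p1", "status": "ok", "smiles": "...", "natoms": 12, "alts": 1}

When a transform matches several sites, the product with the
lexicographically smallest canonical SMILES is kept and the number of
distinct alternatives reported, so outputs are deterministic.
"""
import sys
import json

from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem

RDLogger.DisableLog("rdApp.*")

_RXN_CACHE = {}


def _rxn(smarts):
    r = _RXN_CACHE.get(smarts)
    if r is None:
        r = AllChem.ReactionFromSmarts(smarts)
        _RXN_CACHE[smarts] = r
    return r


def apply_step(mol, smarts, bb_smiles):
    rxn = _rxn(smarts)
    if bb_smiles:
        bb = Chem.MolFromSmiles(bb_smiles)
        if bb is None:
            return None, 0, "bb_parse"
        reactants = (mol, bb)
    else:
        reactants = (mol,)
    if rxn.GetNumReactantTemplates() != len(reactants):
        return None, 0, "arity"
    prods = set()
    for pset in rxn.RunReactants(reactants):
        p = pset[0]
        try:
            Chem.SanitizeMol(p)
            prods.add(Chem.MolToSmiles(p))
        except Exception:
            continue
    if not prods:
        return None, 0, "no_match"
    best = sorted(prods)[0]
    return Chem.MolFromSmiles(best), len(prods), None


def main():
    out = sys.stdout
    for line in sys.stdin:
        line = line.strip()
        if not line:
            continue
        job = json.loads(line)
        mol = Chem.MolFromSmiles(job["start"])
        rec = {"id": job["id"], "status": "ok", "smiles": None,
               "natoms": None, "alts": 1}
        if mol is None:
            rec["status"] = "start_parse"
        else:
            max_alts = 1
            for step in job.get("steps", []):
                smarts = step[0]
                bb = step[1] if len(step) > 1 else None
                mol, nalt, err = apply_step(mol, smarts, bb)
                if err is not None:
                    rec["status"] = err
                    mol = None
                    break
                max_alts = max(max_alts, nalt)
            if mol is not None:
                rec["smiles"] = Chem.MolToSmiles(mol)
                rec["natoms"] = mol.GetNumHeavyAtoms()
                rec["alts"] = max_alts
        out.write(json.dumps(rec) + "\n")


if __name__ == "__main__":
    main()
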