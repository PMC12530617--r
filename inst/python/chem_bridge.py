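"""Batched RDKit helper for the moldiff R package.

Reads one JSON request object on stdin, writes one JSON response on stdout.
Tasks: parse, assemble, descriptors, fingerprints.  All molecule-level
failures are reported per entry ({"ok": false, ...}); the process only exits
non-zero on malformed requests.
"""
import json
import os
import sys

from rdkit import Chem, RDConfig, RDLogger
from rdkit.Chem import Descriptors, QED

RDLogger.DisableLog("rdApp.*")

sys.path.append(os.path.join(RDConfig.RDContribDir, "SA_Score"))
import sascorer  # noqa: E402

BOND_ORDERS = {
    1: Chem.BondType.SINGLE,
    2: Chem.BondType.DOUBLE,
    3: Chem.BondType.TRIPLE,
    4: Chem.BondType.AROMATIC,
}
BOND_CODES = {v: k for k, v in BOND_ORDERS.items()}


def clean_mol(smiles):
    mol = Chem.MolFromSmiles(smiles)
    if mol is None:
        return None
    Chem.RemoveStereochemistry(mol)
    for atom in mol.GetAtoms():
        atom.SetIsotope(0)
    return mol


def task_parse(req):
    out = []
    for smi in req["smiles"]:
        mol = clean_mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES: %s" % smi})
            continue
        atoms = [{"el": a.GetSymbol(), "chg": a.GetFormalCharge()}
                 for a in mol.GetAtoms()]
        bonds = []
        for b in mol.GetBonds():
            code = BOND_CODES.get(b.GetBondType())
            if code is None:
                out.append({"ok": False,
                            "error": "unsupported bond type in %s" % smi})
                break
            bonds.append([b.GetBeginAtomIdx() + 1, b.GetEndAtomIdx() + 1, code])
        else:
            out.append({"ok": True, "canonical": Chem.MolToSmiles(mol),
                        "atoms": atoms, "bonds": bonds})
    return out


def task_assemble(req):
    out = []
    for spec in req["mols"]:
        try:
            rw = Chem.RWMol()
            for el, chg in zip(spec["elements"], spec["charges"]):
                atom = Chem.Atom(el)
                atom.SetFormalCharge(int(chg))
                atom.SetNoImplicit(False)
                rw.AddAtom(atom)
            for i, j, code in spec.get("bonds", []):
                rw.AddBond(int(i) - 1, int(j) - 1, BOND_ORDERS[int(code)])
                if int(code) == 4:
                    rw.GetAtomWithIdx(int(i) - 1).SetIsAromatic(True)
                    rw.GetAtomWithIdx(int(j) - 1).SetIsAromatic(True)
                    rw.GetBondBetweenAtoms(int(i) - 1, int(j) - 1).SetIsAromatic(True)
            mol = rw.GetMol()
            Chem.SanitizeMol(mol)
            out.append({"ok": True, "canonical": Chem.MolToSmiles(mol)})
        except Exception as exc:  # sanitization failure => invalid molecule
            out.append({"ok": False, "error": str(exc)})
    return out


def task_descriptors(req):
    out = []
    for smi in req["smiles"]:
        mol = clean_mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES: %s" % smi})
            continue
        try:
            out.append({"ok": True,
                        "qed": QED.qed(mol),
                        "sas": sascorer.calculateScore(mol),
                        "logp": Descriptors.MolLogP(mol),
                        "tpsa": Descriptors.TPSA(mol)})
        except Exception as exc:
            out.append({"ok": False, "error": str(exc)})
    return out


def task_fingerprints(req):
    from rdkit.Chem import rdFingerprintGenerator
    gen = rdFingerprintGenerator.GetMorganGenerator(
        radius=int(req.get("radius", 2)), fpSize=int(req.get("nbits", 2048)))
    out = []
    for smi in req["smiles"]:
        mol = clean_mol(smi)
        if mol is None:
            out.append({"ok": False, "error": "unparsable SMILES: %s" % smi})
            continue
        fp = gen.GetFingerprint(mol)
        out.append({"ok": True, "bits": [int(b) for b in fp.GetOnBits()]})
    return out


TASKS = {
    "parse": task_parse,
    "assemble": task_assemble,
    "descriptors": task_descriptors,
    "fingerprints": task_fingerprints,
}


def main():
    req = json.load(sys.stdin)
    fn = TASKS.get(req.get("task"))
    if fn is None:
        raise SystemExit("unknown task: %r" % req.get("task"))
    json.dump(fn(req), sys.stdout)


if __name__ == "__main__":
    main()
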