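precursor	peptide	sequence	mh_printed	modifications	comment	analyzable
Acyl-CoA binding protein	ODN peptide	TVGDVNTDRPGMLDF	1637.56			yes
Cerebellin-1 pre.	Cerebellin-1	SGSAKVAFSAIRSTNH	1632.85			yes
Cerebellin-2 pre.	Cerebellin-2	SGSAKVAFSATRSTNH	1620.80			no
Cerebellin-4 pre.	Cerebellin-4	ANSKVAFSAVRSTN	1451.70			yes
Cerebellin-4 pre.	Cerebellin-4	SKVAFSAVRSTN	1267.36			yes
Gastrin-releasing peptide	GRP	APLQPGGSPALTKIYPR	1766.69			yes
Gastrin-releasing peptide	GRP	APLQPGGSPALTKIYP	1608.89			no
Gonadotropin-inhibiting hormone	GnIH propep	SVPISLSQGVQESEPGM	1743.83			no
Gonadotropin-inhibiting hormone	GnIH-RP2	SPLARSSIQSLLNLPQ	1723.97			no
Gonadotropin-inhibiting hormone	GnIH-RP2	ARSSIQSLLNLPQ	1426.80		printed elsewhere as ARSSIQSLLNLSQ	yes
Glucagon family neuropeptides	PACAP27	HIDGIFTDSYSRY	1573.73			no
Neuropeptide Y (NPY) pre.	NPY	SSPETLISDLLLR	1443.81			no
Prepronociceptin (PNOC) pre	Precursor	AVASPLQVSELL	1226.82			yes
Prepronociceptin (PNOC) pre	Nociceptin	YGGFIGVRKSARKWNNQ	1981.07			yes
Prepronociceptin (PNOC) pre	Nociceptin	YGGFIGVRKSA	1154.63			yes
Prepronociceptin (PNOC) pre	Nociceptin	YGGFIGVRK	996.56			no
Prepronociceptin (PNOC) pre	Neuropeptide1	GSWPAARGVQ	1981.05			yes
Prepronociceptin (PNOC) pre	Neuropeptide2	FSEFLKQYLGMSPR	1702.86			yes
Prepronociceptin (PNOC) pre	Neuropeptide2	SEFLKQYLGMSPR	1555.79			yes
Proenkephalin A (PENK) pre	Precursor	MDELYHPESEDEANGGEILA	2218.94			no
Proenkephalin A (PENK) pre	Precursor	MDELYHPESEDEANGGEIL	2147.91			no
Proenkephalin A (PENK) pre	Precursor	DELYHPESEDEANGGEILA	2087.90			no
Proenkephalin A (PENK) pre	Precursor	ELYHPESEDEANGGEILA	1972.44			yes
Proenkephalin A (PENK) pre	Precursor	ELYHPESEDEANGGEIL	1901.84			no
Proenkephalin A (PENK) pre	Precursor	LYHPESEDEANGGEILA	1843.83			no
Proenkephalin A (PENK) pre	Precursor	YHPESEDEANGGEILA	1730.75			no
Proenkephalin A (PENK) pre	Precursor	YHPESEDEANGGEIL	1659.72			no
Proenkephalin A (PENK) pre	Precursor	HPESEDEANGGEIL	1496.65			no
Proenkephalin A (PENK) pre	Precursor	VGRPEWWLDYQ	1448.69			yes
Proenkephalin A (PENK) pre	Precursor	SPELEDEAKELQ	1387.62			yes
Proenkephalin A (PENK) pre	Precursor	SPELEDEAKEL	1259.90			yes
Proenkephalin A (PENK) pre	Precursor	ELEDEAKELQ	1203.57			no
Proenkephalin A (PENK) pre	Precursor	LEDEAKELQ	1074.99			yes
Proenkephalin A (PENK) pre	MERF	YGGFMRF	877.40			yes
Proenkephalin A (PENK) pre	MERSL	YGGFMRSL	930.45			yes
Proenkephalin B (PENK) pre	Precursor	PKLKWDNQ	1028.80			yes
Protachykinin 1 (PPT) pre	C-term flanking peptide (CTFP)	SLNSGSSERSIAQNYE	1741.07			yes
Protachykinin 1 (PPT) pre	C-term flanking peptide (CTFP)	SLNSGSSERSIAQNYE	1821.77	phospho@6	S6/7(p)	yes
Protachykinin 1 (PPT) pre	C-term flanking peptide (CTFP)	SLNSGSSERSIAQNYE	1900.26	phospho@6;phospho@10	S6/7, S10(p)	yes
Protachykinin 1 (PPT) pre	Substance P	RPRPQQFFGLM			MH+ not printed; sequence as printed in the differential table	yes
Protachykinin 1 (PPT) pre	Neuropeptide K	DAGYGQISH	947.42			yes
Protachykinin 1 (PPT) pre	Neuropeptide K	AGYGQISH	832.40			no
Protachykinin 1 (PPT) pre	Neurokinin A	HKTDSFVGLM	1133.87	amide@cterm	M-amide	yes
Secretogranin-1 pre	Secretogranin1- propep	QYDKMDQLAQLLNY	1725.81	pyroglu@nterm	Pyroglutamic Acid	no
Secretogranin-1 pre	Secretogranin1	IHEGEEGEAEEE	1357.54			yes
Secretogranin-2 pre	Secretoneurin	TNEIVEEQYTPQSLATLE	2064.99			no
Secretogranin-2 pre	Secretoneurin	TNEIVEEQYTPQSL	1650.79			yes
Secretogranin-2 pre	Secretoneurin	TNEIVEEQYTPQS	1537.70			no
Secretogranin-2 pre	Secretogranin2	SGKLSFLEDEM	1255.59			no
Secretogranin-2 pre	Secretogranin2	SGKLSFLEDE	1124.55			yes
Secretogranin-2 pre	Secretogranin2	SGKLSFLE	880.478			no
Secretogranin-5 pre	C-terminal peptide (CTP)	SVNPYLQGKRLDNVVA	1772.96			yes
Secretogranin-5 pre	C-terminal peptide (CTP)	SVNPYLQGKRLDNVV	1701.63			yes
Somatostatin pre	SMS-propep	SLAAAAGKQELAK	1256.71			no
Somatostatin pre	SMS-14	KNFFWKTFTSC	1409.18			yes
Somatostatin pre	SMS-14	FWKTFTSC	1019.90			yes
Somatostatin pre	SMS-28	SANSNPALAPRE	1226.61			yes
Somatostatin pre	SMS-28	SANSNPALAPR	1097.57			no
Somatostatin pre	SMS-28	ANSNPALAPRE	1139.58			no
Vasoactive intestinal peptide	VIP	AVFTDNYSRF	1219.7			yes
CRMP-2		APPGGRANITSLG	1210.81			yes
FKBP5		ANAGPNTNGSQFFICTA	1712.77			yes
Stathmin		ASGQAFELILGPR	1358.74			no
Thymosin beta		SDKPDMAEIEKFDK	1566.84			yes
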