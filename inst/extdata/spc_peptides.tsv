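id	sequence	description
SP-C human	FGIPCCPVHLKRLLIVVVVVVLIVVVIVGALLMGL	Native human SP-C (35 aa); Cys-5/Cys-6 palmitoylated in vivo (palmitoyls not modelled)
SP-C dog	FGIPFCPVHLKRLLIVVVVVVLIVVVIVGALLMGL	Native dog SP-C (35 aa); one palmitoylcysteine replaced by Phe in the native sequence; synthetic stand-in transcription on the human scaffold
SP-C pig	LRIPCCPVNLKRLLVVVVVVVLVVVVIVGALLMGL	Native pig SP-C (35 aa); sequence of the 1SPF NMR construct
rSP-C	GIPFFPVHLKRLLIVVVVVVLIVVVIVGALLIGL	Recombinant human SP-C mimic (34 aa): Phe replacing Cys-4/Cys-5 and Ile replacing Met-32
SP-Css	GIPSSPVHLKRLLIVVVVVVLIVVVIVGALLMGL	First-generation mimic (34 aa): human scaffold with Ser replacing the palmitoylcysteines
SP-Cff	GIPFFPVHLKRLLIVVVVVVLIVVVIVGALLMGL	First-generation mimic (34 aa): human scaffold with Phe replacing the palmitoylcysteines
SP-Css ion-lock 1	GIPSSPVHLKRLLIVVVVVELIVKVIVGALLMGL	SP-Css(E20/K24): single Glu(-)-20 / Lys(+)-24 salt bridge in the poly-Val midsection
SP-Cff ion-lock 1	GIPFFPVHLKRLLIVVVVVELIVKVIVGALLMGL	SP-Cff(E20/K24): single Glu(-)-20 / Lys(+)-24 salt bridge in the poly-Val midsection
SP-C33 UCLA	IPSSPVHLKRLKLLLLLLLLILLLILGALLMGL	Second-generation mimic (33 aa): poly-Leu replaces poly-Val; same sequence as conventional SP-C33
SP-C33 ion-lock 1	IPSSPVHLKRLKLLLLLLLEILLKILGALLMGL	SP-C33(E20/K24): single Glu(-)-20 / Lys(+)-24 salt bridge
SP-C33 ion-lock 2	IPSSPVHLKRLKLLKLLLEEILLKILGALLMGL	SP-C33(K15/E19; E20/K24): double salt bridge Lys(+)-15/Glu(-)-19 plus Glu(-)-20/Lys(+)-24
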