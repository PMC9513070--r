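>traB_seed1 synthetic aligned seed
ETDLCNRAGGEEGPYDGKVQSSSPLRNLEIEAELELFQKYKEHALCSTLRLVGQRGMTKF
FNICISRGPVGELIDTGKDARVFREIVDSVTAWILIVLNLIKILELKTKVLDGVNLHCAI
TYGEQVSTSAIDANTLSGIAVSGGQSPRDTGIELYDNTIVRVEPVVPSDTSGRNCDTMEG
KPCCIIRVQYPALKKANFPDAPHESRAKVDAFMQADKIDFANYSGTNEGSTNLSVFSSEF
QHTGMSDSQAEHRFLVIEVGTARESQKVHEYDNEPCTRTQVIECKNVTDSAGSGLHRQAS
PLYYGTLYPGEDEEDIDPYFPLAKLAGPMGLRSEAQGKSRPEPFDSRQGRALADTEAPNT
QPSTFSMEKSGCFVKERQALTRSGILQVAAGAAPNGELRAGCGKNLPAYELPFSILDVII
EFGCPSEYACWCAYNGGEISIQANTMEKPVDTALQPDNTTTGAYRDGYPTNIVVYEAFSG
ITNLRALALLNMQPRLDSGVEGLKQWNYIGTAKTDIGVQGSLEDSKDIDETFTGASHERN
TIPTTQPSGNPALAEHDPVEAKPKELGTSTIKLRLHTLDPMYTGTGAHVEQVKDGSHAYV
RPTGDDEYFFYRDLSAQPGNELTGIPSLAKGQESRKTAATPLRLSGTFVCGIKVSLGNMN
VSVKGYKDDGLADPDLNIIQLQNFLSSSGWDRSFNTLIHKVQAHFMPSHPELIMGNSREM
EQEHVLAQGQVGFLDSWD
>traB_seed2 synthetic aligned seed
ETMLCVRAGQEEGPDDGKVDGSSPLRNLDIEAQTELFQKYKEHALDSTLRLIGQRGMTKF
FNICISRGPVGEWHICRKDARYFREIRDSSTAWILIVLNLIKILEWQTKVLLGVNLHCAI
TYGEQVSTSIIDANTLSGIAVSGGQSPRDTMIELYDNTIVRVEPVVPSDTSGRYCDLMEG
KPTCIIRVNYAYLVKDIKPDAPMESRAKVDAFMQADPIDFANYSGTNEGSTNLSNFSSEF
QHWGMSDSQAEHRFLVIEVGTARESKKVHEYDNEPCTRRYVIECKNVHDSAGSWEHRQAS
PLYQGRLYPGRNEEDHDPYFPLKNLAGPMGLRSEAQYKSRPEPPDLHMGRALADTEAPNW
QPSTFSMEKSGCFVKERQALTRSGILQVAAGAAPFGELRAGSCKNWPPMELPFSILDVII
ITGCPSEYACQCAYNHGDISIYANTMEKPVITFLQPDNTTTGAYRDGYPPNIVVYEAFSG
ITNLRALACLAGQTRLDSGVEGLKQWNKIGTAKTDIGVQGSLEDPKDIDETFTGASHARN
TIPTTQPSGNPALAEHQLEEAKPKILGTSTIKWRLMTLDPMYTGLNAHVEQVKSGSHGYV
IPKGDDEYFNYRDESAQPGNELPGIPVLATGVESRKTAATPDELSGTQVCGIKVSLENMN
VSVKGYKDDGLAQPDLNIIQLQNFLSSSGWDRMFNTLIHKVQADFRPSHTEWIMGNSRDM
EQEHVLWGGQVGFLDYWD
>traB_seed3 synthetic aligned seed
ETDLKCRAGGEEGPYDGKVQSCSPLRKLEAEAELELFFKYKEHALCSELRQVGPRGMTKF
ANICISLGPSGELIDCGKDDRFFREIVDSVTAWFLIDLNLIKILGLKTKVLDGVNLHHAI
TYGEEADTSAIDANTLSGLAVSQGQSPRDTGIELYDNTIHVVEPVVPSDSSSRNCDTMEG
KPCCIIRVQPPALKKAFFFKAPHESRAPVDAFMTACKIDTANYSGTNEGSTNLSVFSSEI
FHTAMSDSQAEHRFLVIESGTAREYIIAHAYDNEPCTRTQVIECKNVTWSAGSGLYRQAS
PEYYGTLYPGEDPEDIDPYEPLAKLAGPMGLRSEAQGNSRPEPFDSRQGRALQDTEAPND
QPSTFSMEKSGCFVPERQALTRLGILHYAEGAAPNGELRAGPGKNLPQYELPFSILDVIT
EFGLPSAYACWHAYNGSIISIQANTHEKPVDIAIQPDNTTTGAYADHDPTNIVVMEAFSG
ITNLRDLCLLNPQPRLDSGVEGLTQWNYIGTAKTDIGVQGSRGYSKPIDSTFTGASHERN
TIPTLQPLGNPELAEHDPVEAKPKELGTSTIKLRLHTLDPMYTGTWARVEQVKDGKHAYV
GPRGLDEYFFYVDCVAQPGNELTGIPSLAKGQESRKIAFTWWRLVGPMVCGIKVSLGNMN
VSWKGYKDDLLADPDLNIIQLQYFLSSDGRDRLFNTLIHKVQWHFMPSHPELIMGNSREM
EQPAVLAAGQVGFLDSWD
>traB_seed4 synthetic aligned seed
ETDLMNRAFGEEGPLDHAYQSYSQLRNLEWEAELELFQKYKQHALCLTLRLVGQRGMIKF
FNICHSRGTVGLLIDTGCDARYAREIVDSVTAWILIVLNLIKELELKTKVLDDVNLHWAI
MWMEQVITSAGDANQLSHMAVSFGQNPRDTVIELYDNTIVRVEPVVPSDTRGRNCDTMEG
KPCCRIRTQYPALKKANFRDNPHESRAKVDAFMQACKIDFANWSGTYEHSTNLAVPWSEF
EHTGMMDSQAMHKFYCREVGTARESQEVHEYDNEPCTRTQVIECKNVTDSAGSGLHCQAS
PLYYGTLMPGEDKVDMDPYFPKAKLAGPMGLRSEAKGKSRCEWFDSAQGRALADTEAPNK
QPSEFSAGKSGCFVKERQALTRSGIGNVAAHAAPNGELRKGCGKNLPMVELPIMILIVIQ
VFGCPSEYACWCAYNGTEIPIQANSMEKGVDTATQPDNTTWGAMRDMYPTNIVVYEAFSG
ITNLRALALVNMQPRLMSGVEGLKTWNYIGTYATDIFVQGSLIDSKDIDEGFTGASHEHN
LIPTTQPSGNPVLAEHDPVEAKPKELGTSTIKLRLHTGDPMYTGTGASVEQVKDGSHMYV
RPYGDDIYFFYRDLSAQPGNELTGIPSLAKGQESRKTAATYLRLSGTFVCGIKVSLGNMN
VSVKGYEDDGLADPDLNWIQLQNFLSSSFLDRSFNILIHKVDAHFMPSHEELIMANSREL
EQEHVLAQGQVGFLDSWD
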