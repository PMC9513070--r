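>integrase_tyr synthetic canonical seed
NNSDRKIAAPEVELQNFVTERLTIEELYPKSIDCSNIGKSNKKVWRLCIFKNSGFEDGDR
WQEGIEIKDNQFRTESLPPATSNLSIQWTCIWMWLTKPASYRALDGKFRSLKLRGTFLNA
FWVLSNDSSLFLEHRPLTGDILGEPLRLTSAYLKLTLGQHLCDDSSGISLVYPIREELGH
GETQGDEKAGISQDSLIENSGARKFCAVEFHTGRAGGLLSNSKRTHADTSPQDTLNKASA
ARRYKYKKEESAVAAAGNKSIILVYWYWEQAGNILISDAVRWRKQFQKILIYPFQKIRYN
NDRGRLQCRRDKPAVNSLDLLLLLDLPMLAIPEIEPKGKMAYEGQGEDLAGNGIKAGPCS
PVLEEGNVTVILDREVLDEG
>integrase_ser synthetic canonical seed
QTEFKGQYSGFSMETEEVEFGNEMKSKRSSNFPKENYHARTEHQACKHSLIMESIRLEEH
GVMSNCSSALLKEGEKEGCDRRNGYPYRQAKTKNCLLWLKIDTFPKKEQEGDHAKMERSA
VMNEPSNSDEISSNQSTMAPLGGDQRDPSGLKLMATFQPLKSQVANVSGKAPHHVRVGPP
DLREDNTSYPVMGAAAADLHAQNPCAEINDDEIRYNVLDAGVLNPLESAVQGSLEALEIC
VARPEIDNAPSGIERFAEPVYPYGKERSLESTVSVSVWPTVGVHIIAPGESGRNLQRDRH
EKEYAGFQKVCARADVEGSTCVAKQSSEALICLRKLGDHNVTESAQIISILPGLTSAPPM
DLGEAKIAIPQIGAPAPQIWGPLTENDEMVIKTSRDAFGSEPNAFVSKRQDTIFLLWDLK
YVLCAGNYDEEINEEDPAPRPNPLYEFGDVIPLLRLQARWPYMMYNESILGRCRTQNATE
>relaxase synthetic canonical seed
KSGSGLETQTERLSLEDRMLEFEALEEINGILHEKPYQGFSRDLGVEYGANTIVDNALQG
VAHVNKRTENACLGSVPAAFLGNERNLYGQFIATIPKFQMMIEATAGSSKIREQEETTSY
GSEQEQVSRRGGTNVLRRPDGYMWVALSVFPTKPVPDTILVVTQAPSLINNYKRYQEDPL
AAQLSHFDTIHAAAALMPSFQDFDKTVKLYAWVPRHALELEPTSCIIFDADQVLIRKQMA
EQIKTAFKGRLIPTLIDECLKLDIDGKKYTEDLKNNLIKQFKTVLKMGDKKQNNFGTIEE
VESNIQNKGWGTSQRLKTDSKQYRGKTMFEAPWFDVTKET
>coupling synthetic canonical seed
GTEAMALMWQLGHDPPPHFLVENGQSTILVGRNIRLIFLSFDKGSANLKATNIPVELGIE
VFLSRVGTPTVLVGEGTKFAQEVSCNDDKMSTDKRNLLGYRGNQVDPMYLEYVFLKIREK
KETLKKGLVERPYKMFLPSRQFIYTRPLYCACLEGYNTYSVRPIQDHKRYFGFHPMSYFE
FAPSLIRVPLKHPAASVNAEIFSAHLGRRGEAETFACACGGYDFCSDGMLEVMSGNRKLH
SFPEHVIGHSKITSPTCLPELPQDFIIRRFEVGRITDEILEGPKKAQCLKDDKLEQQGCI
ESTGETARYVELGKPKAESSRSMLDDADYYNNYIFYLAYVLVQQRGNLGLAAGNTDVHLL
EAKVQVAYELKEEPDEDACDVGATMNTMFLVAFFSLLLGAMAFVSIGDPNWMFGLLNIMD
LHTLLLSHGALGQTTKPKPFTKLVRTDRWSESADGLGWIVLEWVAPNITTGDSPGLFISL
VPSAEETATPDPNHDRIRNYKTVFGRGGGDGKIIFTTEEEEERSKEPGNKDHTEGDSEDT
>virb4 synthetic canonical seed
LNYTPPIDGAEQGLKIIHITSFGRNSVVTMGFMEGKKCLIAEKLDRPNFTTSTATNHTRQ
AFLISASLTERDIKHQEINAQEKVQGATFECLPNSFLPGTGTCHMNCYEKGLKTALQNKL
KVFSVPSAKIEEMTNIFTNHISLIINRASESDKVWQTVDVESCLYKNDFIEYRMLGYRQL
RILKPIAGHWKPRCRSLVSMSTECDDSHDMLRLFSQKAEMDSTKVRDDKVISYVLRGHLI
NCANRRADPECGFKGGLDCPTNKHTLDHQARVCAMYCTNLVQATPHELIEYNFKNGPNNH
RNTRIAHMAVKPSDRCDFYELRTGTDVAYDDLGGGNEVGSRRVKLYSDKGSQAAGMGCAP
TVTQNDLESSRRADYTKHVIMYEKSDVKYIKTTGTFKDGGWASVRPNQCKTKKLCNIFSE
LATIVRLAPLRSKNNTWFSGYPQERILSEKFGTVEGSSISIRDQGAPCALFSKKANYSDL
QHQDLNAVHRLCLKGNTELLNALKKFMGVAQLHGSPNVESNFVSHQHRGVVQVVTKNRTE
QSARERNSRGRCKVYLAPIPYLNAVAGGGLGPVSTNLQEYLMARTYLHKPRLKIAARSLT
EVQEAADYDEPIHLVARKTLMPNPTRWAGENILQRTKKWTNPDLIMDLKIHPSSLPSQEC
NTNMVTPVLGPDMKTYELKGDSSAGVPAEPTPFAGLTLQVVVDELHVQLLLTTLRNNHSY
GNCNYAPYFELIAWLRVHVDAAKPTKTLIATPVTVKRIAD
>traB synthetic canonical seed
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
>rep synthetic canonical seed
LHKHDAALKATTLPAKRGFGTYDGPWKAKEQELGHGDINETNTSSVPCGKSDPVTHSELY
KDMANGDALVIRLGNSGTYVCAMIIPPTEPCYMRSADPVYPSSVDTTSLKTLLLAPCTFL
QSTVLLHAADADAGQNLACIFPFERTESEKLKLGMSNEKTSDKSASECANHHVAVRPKGA
GKAQDLVQVGRVPFFGEGQEVCIGLLLNCAPQVPWKIRDARGHRLLLPRIDFERKKLANG
NPELLRPDVLMYQQSTESYPGNLYHRGENILSDCSTVAGLAWLVCNLDHNLGVVVYPPNY
SASLESSGQPSITKASALDY
>parM synthetic canonical seed
RTIKSSTGSQATEAYTVSFGGVPREDMAVIQKELANPRDSVAQPRTEPKKKFVEDSMEID
IGFLGSQRSVDRSLGMELVFAPSITSAPVVDIINITNTESSGKSFGCKRSYTECLTEQLL
CNIKNGSEAIEGLQKTTKTLNGATTAKSYSGEDLLTPDKIHVALVAAGKDEHVNGHPKAT
DAVDLKQNRVLDYFKVHEMRSQSQPGMVGDTKTFSIFPNDWKYAGDDEEPLILRKGPDMP
VVRGFRGSTRILSGNIITDLSRLAFKDIRHKWLTAVENSAYVDYLNDSLHLGALAPARAD
>atp_gtp_binding synthetic canonical seed
VTPRYRAYHGTTRLRCLGQIHAPVVFLGYVNDLDKGAECSCLFNRQKFMLIGPDEFPGAG
SDKQRSLEDLPKRQLRRQMLRAVVIAMWKEYDPQVCEKICDTAQETHGERVAFRWEDPDP
QWLPINYFKGFAEIEALELKPDTYGSTIINGHGRRLRFRPADQCEDVSETADRDERKVVP
FHESGLRLLESQYGSRPSDR
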