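>MAN1A1_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
NDAVRNIVILFECINHDKQYEKERDLIALHMNLQWNYHRSDNDGENTWKDSTTPWLFLTV
HMEWESCFRCLRDIARDRVAIIFWDWTGGYEGIICQARLFMRAAAIVPKAVLGEIMTMCH
>MGAT2_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
SKYERQVYPHWNNCLRHTGALSYYHDSHTVPVHGMDIFHYAWEDTMEIRRMPMWWTTGWW
GAQQHCKLEAMFANMPAAGYGYGIWSEIMEWEPMTNMNTPDEDHHSNYMGPPNFEELGSR
>ST6GAL1_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
PNWQTSDILQADYKETHVHGQGTFQDEKPWLPMTKFHDYQWKHMVPPGSSAETCRIFASY
IKCWCCNRCDCLCAYIPNPSYTKAKVFNCQKHEPNYVLTKIILCQPGKFLFGWQPHRVNY
>ALG1_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
WWAWEQKMIVSHCEWMCDYFVMMDINWAGSHMWVQHRADNFGRNFLPCCQNKSRSLRHMP
DYQWKASRVKAQKQFCYYSMRAQFCIAGYFMYRDKMCQEFSDQRAAPTWKNHQCSRNVSV
>BC2LC_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
KHDFYEFMAEPTVKTTFCKKHTFWLESWKQGIMGDRRPCMVVSCKFHGARHVLWMNQGPM
SIQWHAINWVGSRAPKYLRLWLKFKIWDFWSHNADQFMDEMTRHEENIRY
>EPO_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
RLQWEEAGSPLKLNGFSWPVVTFNATYWRHKWQGNVMNATFHIFEDGRSFLRMKTGYAKW
AWSDLVFSSMSGKSRRMHHVDYNATTGTTLDRPADLTYRCRRIYDVIQSIHKTCCHEHKQ
KCDTDSSHIKKTWTVRRAERETSDGSHCGLYQWHLDFNQCTILQVR
>GPC1_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
VISFACTTLWVHGYVCMFIIYQSSWSNGPLFKFRIEWGHSSMCLKHIHELVSVHGYNKWS
EGECRWIYTGYGQYGSMGYDVKRKHYPGMCAFKIDYEWYSQCNKSIRIKYAIHQEFFICC
PYHQCLRNRS
>BIKUNIN_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
QRNDYTDSESYCPHERAQDMYNGLVIVRSGATHFFWLSMELHRKQNAYHHPSHSSTKSFS
MSNEAQAAVRRHMWETFWPTEHAVHVENRWSYAIVKWNPH
>DAG1_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
GGRWCVMKCNLDTGQGNRCMWLNCWSFFSTIAMTPRQISAYTVKTTQPHEWMMGWTWKDE
CFCHIRFWFYIKADVVRCLMQHILPLLYQGEPESYACWFIMYQGGQRYFVPNHRCAYWEY
>SIGLEC2_synthetic synthetic stand-in sequence (deterministic, seed 20240301)
MDHPNQMFWNMTGFSKVIGLEYEADIGYAPGCNGVQQKEGMMMKNHRPKQGLKKMKCLTT
VWIIYENATPHDRGSVDAHWMKSIVKRGNITWYVCWNATWNATEYLGYFPMNATNSQFWK
FGEKVSIFYTMMPINATYVTGKQYEMHGDVLDSPMWKNIVCDRNATHECFCAGQGLVAFV
MPWKNATQAFYVLDFDAEGMVWYNMNATGGGQPTMYSLNPWVSLMGTVAWNATEPGHGDH
VFNLAGFKLAHNATTPVISDQLDILNEMLHMMQMNATEEGLIWCWMLHARRNATWMRDWF
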