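<?xml version="1.0" encoding="UTF-8"?>
<COCHRANE_REVIEW REVIEW_ID="SR0002" VERSION="5.3">
  <COVER_SHEET>
    <TITLE>aripiprazole versus placebo for schizophrenia</TITLE>
  </COVER_SHEET>
  <STUDIES_AND_REFERENCES>
    <STUDIES>
      <INCLUDED_STUDIES>
        <STUDY ID="Olsen 2012" NAME="Olsen 2012">
          <REFERENCE ID="REF-Olsen-2012-1">
            <TI>Report 1 of trial Olsen 2012</TI>
            <SO>Br J Psychiatry</SO>
            <YR>2012</YR>
          </REFERENCE>
        </STUDY>
        <STUDY ID="Dimitrov 1963" NAME="Dimitrov 1963">
          <REFERENCE ID="REF-Dimitrov-1963-1">
            <TI>Report 1 of trial Dimitrov 1963</TI>
            <SO>Schizophr Res</SO>
            <YR>1963</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Dimitrov-1963-2">
            <TI>Report 2 of trial Dimitrov 1963</TI>
            <SO>Schizophr Res</SO>
            <YR>1965</YR>
          </REFERENCE>
        </STUDY>
        <STUDY ID="Jones 1990" NAME="Jones 1990">
          <REFERENCE ID="REF-Jones-1990-1">
            <TI>Report 1 of trial Jones 1990</TI>
            <SO>Br J Psychiatry</SO>
            <YR>1990</YR>
          </REFERENCE>
        </STUDY>
      </INCLUDED_STUDIES>
    </STUDIES>
  </STUDIES_AND_REFERENCES>
  <CHARACTERISTICS_OF_STUDIES>
    <CHARACTERISTICS_OF_INCLUDED_STUDIES>
      <INCLUDED_CHAR STUDY_ID="Olsen 2012">
        <CHAR_METHODS>
          <P>Allocation: allocation by date of birth. Blinding: single-blind. Duration: 4 weeks.</P>
        </CHAR_METHODS>
        <CHAR_PARTICIPANTS>
          <P>N=68 outpatients with schizophrenia. Mean age 28 years.</P>
        </CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS>
          <P>1. quetiapine: dose 600 mg/day. 2. Placebo.</P>
        </CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES>
          <P>Clinical response, adverse effects and service outcomes reported.</P>
        </CHAR_OUTCOMES>
        <CHAR_NOTES>
          <P>Funding: not stated.</P>
        </CHAR_NOTES>
      </INCLUDED_CHAR>
      <INCLUDED_CHAR STUDY_ID="Dimitrov 1963">
        <CHAR_METHODS>
          <P>Allocation: randomized. Blinding: unblinded. Duration: 8 weeks.</P>
        </CHAR_METHODS>
        <CHAR_PARTICIPANTS>
          <P>N=32 inpatients with schizophrenia. Mean age 28 years.</P>
        </CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS>
          <P>1. amisulpride: dose 220 mg/day. 2. Placebo.</P>
        </CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES>
          <P>Clinical response, adverse effects and service outcomes reported.</P>
        </CHAR_OUTCOMES>
      </INCLUDED_CHAR>
      <INCLUDED_CHAR STUDY_ID="Jones 1990">
        <CHAR_METHODS>
          <P>Allocation: allocation by date of birth. Blinding: double blinded. Duration: 26 weeks.</P>
        </CHAR_METHODS>
        <CHAR_PARTICIPANTS>
          <P>N=96 outpatients with schizophrenia. Mean age 42 years.</P>
        </CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS>
          <P>1. clozapine: dose 520 mg/day. 2. Placebo.</P>
        </CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES>
          <P>Clinical response, adverse effects and service outcomes reported.</P>
        </CHAR_OUTCOMES>
        <CHAR_NOTES>
          <P>Funding: public.</P>
        </CHAR_NOTES>
      </INCLUDED_CHAR>
    </CHARACTERISTICS_OF_INCLUDED_STUDIES>
  </CHARACTERISTICS_OF_STUDIES>
  <QUALITY_ITEMS>
    <QUALITY_ITEM NAME="Selective reporting">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Olsen 2012" RESULT="LOW">
        <DESCRIPTION>Quote: 'selective reporting procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Jones 1990" RESULT="HIGH">
        <DESCRIPTION>Quote: 'selective reporting procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Random sequence generation">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Olsen 2012" RESULT="UNCLEAR">
        <DESCRIPTION>Quote: 'random sequence generation procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Jones 1990" RESULT="UNCLEAR">
        <DESCRIPTION>Quote: 'random sequence generation procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Incomplete outcome data">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Olsen 2012" RESULT="UNCLEAR">
        <DESCRIPTION>Quote: 'incomplete outcome data procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Blinding of participants and personnel">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Olsen 2012" RESULT="LOW">
        <DESCRIPTION>Quote: 'blinding of participants and personnel procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Dimitrov 1963" RESULT="HIGH">
        <DESCRIPTION>Quote: 'blinding of participants and personnel procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Jones 1990" RESULT="LOW">
        <DESCRIPTION>Quote: 'blinding of participants and personnel procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Blinding of outcome assessment">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Dimitrov 1963" RESULT="LOW">
        <DESCRIPTION>Quote: 'blinding of outcome assessment procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Allocation concealment">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Dimitrov 1963" RESULT="LOW">
        <DESCRIPTION>Quote: 'allocation concealment procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
  </QUALITY_ITEMS>
  <ANALYSES_AND_DATA>
    <COMPARISON ID="SR0002.CMP01" NAME="haloperidol versus placebo">
      <DICH_OUTCOME ID="SR0002.CMP01.O001" NAME="adverse effects: anticholinergic">
        <DICH_DATA STUDY_ID="Olsen 2012" EVENTS_1="15" TOTAL_1="27" EVENTS_2="35" TOTAL_2="43"/>
        <DICH_DATA STUDY_ID="Dimitrov 1963" EVENTS_1="31" TOTAL_1="47" EVENTS_2="14" TOTAL_2="27"/>
      </DICH_OUTCOME>
      <CONT_OUTCOME ID="SR0002.CMP01.O002" NAME="Service use: hospital admission">
        <CONT_DATA STUDY_ID="Jones 1990" MEAN_1="52.369999999999997" SD_1="8.1400000000000006" TOTAL_1="41" MEAN_2="34.399999999999999" SD_2="8.0700000000000003" TOTAL_2="22"/>
      </CONT_OUTCOME>
      <CONT_OUTCOME ID="SR0002.CMP01.O003" NAME="Relapse by one year">
        <CONT_DATA STUDY_ID="Dimitrov 1963" MEAN_1="57.729999999999997" SD_1="7.2000000000000002" TOTAL_1="34" MEAN_2="48.609999999999999" SD_2="14.27" TOTAL_2="44"/>
        <CONT_DATA STUDY_ID="Jones 1990" MEAN_1="59.869999999999997" SD_1="3.71" TOTAL_1="20" MEAN_2="52.799999999999997" SD_2="3.6800000000000002" TOTAL_2="45"/>
      </CONT_OUTCOME>
    </COMPARISON>
  </ANALYSES_AND_DATA>
</COCHRANE_REVIEW>
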